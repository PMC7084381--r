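# The character and word attention-enhanced tagger: parameters, batched
# forward pass, backpropagation, prediction, checkpointing.

#' Model configuration
#'
#' Defaults are the published training recipe: 100-dimensional word and
#' character embeddings, CNN filter widths 2/3/4 with 200 total output
#' channels, a 200-dimensional composed word embedding, and a two-layer
#' bidirectional LSTM with 300 hidden units per direction.  Because the
#' word embedding (100) and the composed embedding (200) differ in size,
#' a learned linear projection lifts the word embedding to `d_comp`
#' before the gate, which keeps every printed size intact while making
#' the convex mix well-formed.
#'
#' @param d_word,d_char Embedding dimensions.
#' @param filter_widths CNN filter window widths.
#' @param cnn_output Total CNN output channels (the length of the
#'   character-based embedding).
#' @param d_comp Composed ("new word") embedding size.
#' @param hidden LSTM hidden size per direction.
#' @param num_layers Stacked bidirectional LSTM layers.
#' @param dropout Dropout rate applied to the encoder output before the
#'   label projection (training only).
#' @param cnn_activation Activation of the character CNN.
#' @param emission_mode `"logit"` (default) feeds the raw label-space
#'   projection to the CRF, the standard BiLSTM-CRF wiring;
#'   `"softmax"` first normalizes each row to a probability vector.
#'   Softmax emissions bound every per-token score difference by 1, so
#'   the chain's per-token log-odds are capped and gradients are doubly
#'   squashed; under the fixed training recipe that wiring does not
#'   reach a useful optimum, hence the logit default (see the methods
#'   vignette).
#' @param boundary_transitions Add learned begin/end boundary transition
#'   vectors to the CRF (off by default: the chain score has no boundary
#'   terms).
#' @param char_ablation Force the character-based embedding to zero
#'   (diagnostic: removes the character channel).
#' @return A list of class `cwae_config`.
#' @export
cwae_config <- function(d_word = 100L, d_char = 100L,
                        filter_widths = c(2L, 3L, 4L),
                        cnn_output = 200L, d_comp = 200L, hidden = 300L,
                        num_layers = 2L, dropout = 0.5,
                        cnn_activation = "relu",
                        emission_mode = c("logit", "softmax"),
                        boundary_transitions = FALSE,
                        char_ablation = FALSE) {
  emission_mode <- match.arg(emission_mode)
  stopifnot(d_word >= 1L, d_char >= 1L, cnn_output >= 1L, d_comp >= 1L,
            hidden >= 1L, num_layers >= 1L, dropout >= 0, dropout < 1)
  if (cnn_output != d_comp)
    stop("the convex gate mixes the character-based embedding with the ",
         "projected word embedding elementwise, so cnn_output must equal ",
         "d_comp")
  structure(list(d_word = as.integer(d_word), d_char = as.integer(d_char),
                 filter_widths = sort(as.integer(filter_widths)),
                 cnn_output = as.integer(cnn_output),
                 d_comp = as.integer(d_comp), hidden = as.integer(hidden),
                 num_layers = as.integer(num_layers), dropout = dropout,
                 cnn_activation = cnn_activation,
                 emission_mode = emission_mode,
                 boundary_transitions = isTRUE(boundary_transitions),
                 char_ablation = isTRUE(char_ablation)),
            class = "cwae_config")
}

glorot <- function(n_in, n_out) {
  b <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -b, b), n_in, n_out)
}

#' Build a tagger model
#'
#' Allocates and initializes every parameter tensor.  Embedding rows use
#' the uniform `[-sqrt(3/d), +sqrt(3/d)]` rule ([init_unregistered()]);
#' weight matrices use symmetric-uniform (Glorot) initialization; biases
#' start at zero except the LSTM forget gates (one); CRF transitions
#' start at zero.  The PAD embedding rows are zero and stay zero.
#' Unknown-token rows are drawn once here and then train like any other
#' parameter.
#'
#' @param vocab A [build_vocab()] vocabulary.
#' @param scheme A [label_scheme()].
#' @param config A [cwae_config()].
#' @param seed Integer seed for initialization.
#' @param word_embeddings,char_embeddings Optional pretrained
#'   [embedding_table()]s (e.g. from [cwe_train()]); rows are matched by
#'   token name, tokens absent from the table keep their random rows.
#' @return An object of class `cwae_model`.
#' @export
cwae_model <- function(vocab, scheme, config = cwae_config(), seed = 1L,
                       word_embeddings = NULL, char_embeddings = NULL) {
  cf <- config
  t_n <- scheme$T
  h <- cf$hidden
  nw <- length(cf$filter_widths)
  k <- rep(cf$cnn_output %/% nw, nw)
  if (cf$cnn_output %% nw) k[seq_len(cf$cnn_output %% nw)] <-
      k[seq_len(cf$cnn_output %% nw)] + 1L
  par <- with_seed(seed, {
    p <- list()
    emb <- function(index, d, kind) {
      m <- matrix(0, length(index), d, dimnames = list(names(index), NULL))
      for (i in seq_along(index))
        if (names(index)[i] != pad_token())
          m[i, ] <- init_unregistered(d, kind)
      m
    }
    p$E_w <- emb(vocab$word_index, cf$d_word, "word")
    p$E_c <- emb(vocab$char_index, cf$d_char, "character")
    p$W_proj <- glorot(cf$d_word, cf$d_comp)
    p$b_proj <- rep(0, cf$d_comp)
    for (i in seq_along(cf$filter_widths)) {
      s <- cf$filter_widths[i]
      p[[paste0("conv_W_", s)]] <- glorot(s * cf$d_char, k[i])
      p[[paste0("conv_b_", s)]] <- rep(0, k[i])
    }
    p$W_g <- glorot(2L * cf$d_comp, cf$d_comp)
    p$b_g <- rep(0, cf$d_comp)
    p$U <- glorot(cf$d_comp, cf$d_comp)
    p$b_z <- rep(0, cf$d_comp)
    for (l in seq_len(cf$num_layers)) {
      d_in <- if (l == 1L) cf$d_comp else 2L * h
      for (dr in c("f", "b")) {
        pre <- paste0("lstm_", l, "_", dr, "_")
        p[[paste0(pre, "Wx")]] <- glorot(d_in, 4L * h)
        p[[paste0(pre, "Wh")]] <- glorot(h, 4L * h)
        bias <- rep(0, 4L * h)
        bias[(h + 1L):(2L * h)] <- 1     # forget-gate bias
        p[[paste0(pre, "b")]] <- bias
      }
    }
    p$W_out <- glorot(2L * h, t_n)
    p$b_out <- rep(0, t_n)
    p$A <- matrix(0, t_n, t_n)
    if (cf$boundary_transitions) {
      p$A_begin <- rep(0, t_n)
      p$A_end <- rep(0, t_n)
    }
    p
  })
  apply_pretrained <- function(mat, table) {
    if (is.null(table)) return(mat)
    common <- intersect(rownames(mat), rownames(table$vectors))
    common <- setdiff(common, pad_token())
    mat[common, ] <- table$vectors[common, , drop = FALSE]
    mat
  }
  par$E_w <- apply_pretrained(par$E_w, word_embeddings)
  par$E_c <- apply_pretrained(par$E_c, char_embeddings)
  structure(list(config = cf, scheme = scheme, vocab = vocab, par = par,
                 channels = k),
            class = "cwae_model")
}

#' @export
print.cwae_model <- function(x, ...) {
  np <- sum(vapply(x$par, length, integer(1)))
  cat("<cwae_model> ", length(x$scheme$types), " entity types, ",
      x$scheme$T, " labels, ", format(np, big.mark = ","),
      " parameters\n", sep = "")
  invisible(x)
}

addb <- function(m, b) m + rep(b, each = nrow(m))

softmax_rows <- function(x) {
  x <- x - apply(x, 1L, max)
  e <- exp(x)
  e / rowSums(e)
}

# ---- batch preparation --------------------------------------------------

prepare_batch <- function(model, sentences) {
  cf <- model$config
  n <- length(sentences)
  lens <- vapply(sentences, function(s) length(s$words), integer(1))
  n_tok <- sum(lens)
  t_max <- max(lens)
  idx <- matrix(0L, n, t_max)
  off <- 0L
  for (s in seq_len(n)) {
    idx[s, seq_len(lens[s])] <- off + seq_len(lens[s])
    off <- off + lens[s]
  }
  idx_rev <- matrix(0L, n, t_max)
  for (s in seq_len(n))
    idx_rev[s, seq_len(lens[s])] <- idx[s, lens[s]:1L]
  words <- unlist(lapply(sentences, `[[`, "words"), use.names = FALSE)
  word_rows <- vocab_lookup(words, model$vocab$word_index) + 1L
  chars <- unlist(lapply(sentences, `[[`, "chars"), use.names = FALSE)
  chars_list <- lapply(sentences, `[[`, "chars")
  char_seqs <- do.call(c, chars_list)
  char_seqs <- lapply(char_seqs, function(cs) cs[cs != pad_token()])
  n_real <- lengths(char_seqs)
  w_l <- max(max(n_real), max(cf$filter_widths))
  char_rows <- matrix(1L, n_tok, w_l)    # row 1 = PAD
  for (i in seq_len(n_tok)) {
    cs <- char_seqs[[i]]
    char_rows[i, seq_along(cs)] <-
      vocab_lookup(cs, model$vocab$char_index) + 1L
  }
  y <- lapply(sentences, function(s)
    match(s$labels, model$scheme$labels))
  if (anyNA(unlist(y)))
    stop("sentence label outside the model's label scheme")
  list(n = n, lens = lens, n_tok = n_tok, idx = idx, idx_rev = idx_rev,
       word_rows = word_rows, char_rows = char_rows, n_real = n_real,
       w_l = w_l, y = y)
}

# ---- LSTM (single direction over a padded batch) ------------------------

# Single-direction LSTM over a padded batch.  The sequential
# per-timestep recurrence runs in compiled code (src/kernels.cpp); idx
# maps (sentence, position) to flat token rows, 0 marking padding.
lstm_forward <- function(input, idx, par_pre, h_n, cache = TRUE) {
  .lstm_forward_cpp(input, idx, par_pre$Wx, par_pre$Wh, par_pre$b,
                    h_n, cache)
}

lstm_backward <- function(d_h_out, fwd, input, idx, par_pre, h_n) {
  res <- .lstm_backward_cpp(d_h_out, fwd, input, idx, par_pre$Wx,
                            par_pre$Wh, h_n)
  res$d_b <- as.numeric(res$d_b)
  res
}

lstm_par <- function(par, layer, dir) {
  pre <- paste0("lstm_", layer, "_", dir, "_")
  list(Wx = par[[paste0(pre, "Wx")]],
       Wh = par[[paste0(pre, "Wh")]],
       b = par[[paste0(pre, "b")]])
}

# ---- full forward pass --------------------------------------------------

model_forward <- function(model, batch, train = FALSE, cache = FALSE) {
  par <- model$par; cf <- model$config
  n_tok <- batch$n_tok
  cc <- list()

  # word channel: embedding lookup + projection to d_comp
  xw <- par$E_w[batch$word_rows, , drop = FALSE]
  xp <- addb(xw %*% par$W_proj, par$b_proj)

  # character channel: CNN over the padded character rows
  if (cf$char_ablation) {
    c_i <- matrix(0, n_tok, cf$cnn_output)
  } else {
    w_l <- batch$w_l
    ce <- do.call(cbind, lapply(seq_len(w_l), function(j)
      par$E_c[batch$char_rows[, j], , drop = FALSE]))
    cnn <- vector("list", length(cf$filter_widths))
    for (wi in seq_along(cf$filter_widths)) {
      s <- cf$filter_widths[wi]
      w_k <- par[[paste0("conv_W_", s)]]
      b_k <- par[[paste0("conv_b_", s)]]
      n_pos <- w_l - s + 1L
      k_s <- ncol(w_k)
      best <- matrix(-Inf, n_tok, k_s)
      amax <- matrix(0L, n_tok, k_s)
      pres <- if (cache) vector("list", n_pos) else NULL
      for (p in seq_len(n_pos)) {
        cols <- ((p - 1L) * cf$d_char + 1L):((p + s - 1L) * cf$d_char)
        pre <- addb(ce[, cols, drop = FALSE] %*% w_k, b_k)
        post <- act_fun(cf$cnn_activation)(pre)
        valid <- p <= pmax(batch$n_real - s + 1L, 1L)
        post[!valid, ] <- -Inf
        upd <- post > best
        best[upd] <- post[upd]
        amax[upd] <- p
        if (cache) pres[[p]] <- pre
      }
      cnn[[wi]] <- list(best = best, amax = amax, pres = pres)
    }
    c_i <- do.call(cbind, lapply(cnn, `[[`, "best"))
    if (cache) cc$cnn <- cnn
    cc$ce <- if (cache) ce else NULL
  }

  # attention gate
  xc <- cbind(xp, c_i)
  og <- tanh(addb(xc %*% par$W_g, par$b_g))
  z <- sigmoid(addb(og %*% par$U, par$b_z))
  xbar <- z * xp + (1 - z) * c_i

  # stacked bidirectional LSTM
  layer_in <- xbar
  lstm_caches <- if (cache) vector("list", cf$num_layers) else NULL
  for (l in seq_len(cf$num_layers)) {
    fw <- lstm_forward(layer_in, batch$idx, lstm_par(par, l, "f"),
                       cf$hidden, cache = cache)
    bw <- lstm_forward(layer_in, batch$idx_rev, lstm_par(par, l, "b"),
                       cf$hidden, cache = cache)
    if (cache) lstm_caches[[l]] <- list(fw = fw, bw = bw, input = layer_in)
    layer_in <- cbind(fw$h_out, bw$h_out)
  }
  h_top <- layer_in

  # dropout on the encoder output, then label projection
  if (train && cf$dropout > 0) {
    mask <- (matrix(stats::runif(length(h_top)), nrow(h_top)) >=
               cf$dropout) / (1 - cf$dropout)
    h_drop <- h_top * mask
  } else {
    mask <- NULL
    h_drop <- h_top
  }
  logits <- addb(h_drop %*% par$W_out, par$b_out)
  p_mat <- if (cf$emission_mode == "softmax") softmax_rows(logits)
           else logits

  out <- list(p = p_mat, xp = xp, c_i = c_i, xc = xc, og = og, z = z,
              xbar = xbar, xw = xw, h_top = h_top, h_drop = h_drop,
              mask = mask, logits = logits)
  if (cache) {
    out$lstm <- lstm_caches
    out$cnn_cache <- cc
  }
  out
}

# ---- loss and gradients -------------------------------------------------

zero_like <- function(par) lapply(par, function(p) {
  if (is.matrix(p)) matrix(0, nrow(p), ncol(p)) else rep(0, length(p))
})

#' Mini-batch loss and gradients
#'
#' Runs the full forward pass in training mode and backpropagates the
#' CRF negative log-likelihood (mean over the sentences of the batch)
#' through the projection, encoder, gate, CNN and embeddings.
#'
#' @param model A [cwae_model()].
#' @param sentences List of labelled [ner_sentence()]s (one mini-batch).
#' @param train Apply dropout (default `TRUE`).
#' @return List with `loss` (scalar) and `grads` (named like
#'   `model$par`).
#' @export
model_loss_grads <- function(model, sentences, train = TRUE) {
  par <- model$par; cf <- model$config
  batch <- prepare_batch(model, sentences)
  fw <- model_forward(model, batch, train = train, cache = TRUE)
  g <- zero_like(par)
  n_sent <- batch$n

  # CRF per sentence
  d_p <- matrix(0, batch$n_tok, model$scheme$T)
  loss <- 0
  begin <- if (cf$boundary_transitions) par$A_begin else NULL
  endv <- if (cf$boundary_transitions) par$A_end else NULL
  for (s in seq_len(n_sent)) {
    rows <- batch$idx[s, seq_len(batch$lens[s])]
    p_s <- fw$p[rows, , drop = FALSE]
    cg <- crf_grads_boundary(p_s, par$A, batch$y[[s]], begin, endv)
    loss <- loss + cg$nll / n_sent
    d_p[rows, ] <- cg$d_p / n_sent
    g$A <- g$A + cg$d_a / n_sent
    if (cf$boundary_transitions) {
      g$A_begin <- g$A_begin + cg$d_begin / n_sent
      g$A_end <- g$A_end + cg$d_end / n_sent
    }
  }

  # emissions -> logits
  if (cf$emission_mode == "softmax") {
    d_logits <- fw$p * (d_p - rowSums(d_p * fw$p))
  } else {
    d_logits <- d_p
  }
  g$W_out <- crossprod(fw$h_drop, d_logits)
  g$b_out <- colSums(d_logits)
  d_h <- tcrossprod(d_logits, par$W_out)
  if (!is.null(fw$mask)) d_h <- d_h * fw$mask

  # encoder backward, top layer to bottom
  h_n <- cf$hidden
  for (l in rev(seq_len(cf$num_layers))) {
    lc <- fw$lstm[[l]]
    bk_f <- lstm_backward(d_h[, 1:h_n, drop = FALSE], lc$fw, lc$input,
                          batch$idx, lstm_par(par, l, "f"), h_n)
    bk_b <- lstm_backward(d_h[, (h_n + 1):(2 * h_n), drop = FALSE],
                          lc$bw, lc$input, batch$idx_rev,
                          lstm_par(par, l, "b"), h_n)
    pre_f <- paste0("lstm_", l, "_f_"); pre_b <- paste0("lstm_", l, "_b_")
    g[[paste0(pre_f, "Wx")]] <- bk_f$d_Wx
    g[[paste0(pre_f, "Wh")]] <- bk_f$d_Wh
    g[[paste0(pre_f, "b")]] <- bk_f$d_b
    g[[paste0(pre_b, "Wx")]] <- bk_b$d_Wx
    g[[paste0(pre_b, "Wh")]] <- bk_b$d_Wh
    g[[paste0(pre_b, "b")]] <- bk_b$d_b
    d_h <- bk_f$d_input + bk_b$d_input
  }
  d_xbar <- d_h

  # gate backward
  d_z <- d_xbar * (fw$xp - fw$c_i)
  d_xp <- d_xbar * fw$z
  d_c <- d_xbar * (1 - fw$z)
  d_zpre <- d_z * fw$z * (1 - fw$z)
  g$U <- crossprod(fw$og, d_zpre)
  g$b_z <- colSums(d_zpre)
  d_ogpre <- tcrossprod(d_zpre, par$U) * (1 - fw$og^2)
  g$W_g <- crossprod(fw$xc, d_ogpre)
  g$b_g <- colSums(d_ogpre)
  d_xc <- tcrossprod(d_ogpre, par$W_g)
  d_xp <- d_xp + d_xc[, 1:cf$d_comp, drop = FALSE]
  d_c <- d_c + d_xc[, (cf$d_comp + 1):(2 * cf$d_comp), drop = FALSE]

  # character CNN backward
  if (!cf$char_ablation) {
    ce <- fw$cnn_cache$ce
    d_ce <- matrix(0, nrow(ce), ncol(ce))
    col0 <- 0L
    for (wi in seq_along(cf$filter_widths)) {
      s <- cf$filter_widths[wi]
      cn <- fw$cnn_cache$cnn[[wi]]
      k_s <- ncol(cn$best)
      d_best <- d_c[, (col0 + 1L):(col0 + k_s), drop = FALSE]
      col0 <- col0 + k_s
      n_pos <- batch$w_l - s + 1L
      w_name <- paste0("conv_W_", s); b_name <- paste0("conv_b_", s)
      for (p in seq_len(n_pos)) {
        sel_mat <- cn$amax == p
        if (!any(sel_mat)) next
        pre <- cn$pres[[p]]
        post <- act_fun(cf$cnn_activation)(pre)
        gr <- d_best * sel_mat *
          act_grad(cf$cnn_activation, pre, post)
        cols <- ((p - 1L) * cf$d_char + 1L):((p + s - 1L) * cf$d_char)
        g[[w_name]] <- g[[w_name]] +
          crossprod(ce[, cols, drop = FALSE], gr)
        g[[b_name]] <- g[[b_name]] + colSums(gr)
        d_ce[, cols] <- d_ce[, cols] +
          tcrossprod(gr, par[[w_name]])
      }
    }
    # scatter character gradients back to embedding rows
    for (j in seq_len(batch$w_l)) {
      cols <- ((j - 1L) * cf$d_char + 1L):(j * cf$d_char)
      blk <- d_ce[, cols, drop = FALSE]
      acc <- rowsum(blk, group = batch$char_rows[, j])
      rws <- as.integer(rownames(acc))
      g$E_c[rws, ] <- g$E_c[rws, , drop = FALSE] + acc
    }
    g$E_c[1L, ] <- 0                      # PAD stays zero
  }

  # word channel backward
  g$W_proj <- crossprod(fw$xw, d_xp)
  g$b_proj <- colSums(d_xp)
  d_xw <- tcrossprod(d_xp, par$W_proj)
  acc <- rowsum(d_xw, group = batch$word_rows)
  rws <- as.integer(rownames(acc))
  g$E_w[rws, ] <- g$E_w[rws, , drop = FALSE] + acc
  g$E_w[1L, ] <- 0                        # PAD stays zero

  list(loss = loss, grads = g)
}

# CRF gradients with optional boundary transition vectors.
crf_grads_boundary <- function(p, a, y, begin = NULL, endv = NULL) {
  if (is.null(begin) && is.null(endv)) return(crf_grads(p, a, y))
  m <- nrow(p); t_n <- ncol(p)
  alpha <- matrix(0, m, t_n)
  alpha[1L, ] <- p[1L, ] + begin
  for (i in seq_len(m)[-1L])
    alpha[i, ] <- apply(alpha[i - 1L, ] + a, 2L, logsumexp) + p[i, ]
  beta <- matrix(0, m, t_n)
  beta[m, ] <- endv
  if (m > 1L) for (i in (m - 1L):1L)
    beta[i, ] <- apply(sweep(a, 2L, p[i + 1L, ] + beta[i + 1L, ], `+`),
                       1L, logsumexp)
  logz <- logsumexp(alpha[m, ] + endv)
  marg <- exp(alpha + beta - logz)
  d_p <- marg
  d_p[cbind(seq_len(m), y)] <- d_p[cbind(seq_len(m), y)] - 1
  d_a <- matrix(0, t_n, t_n)
  if (m > 1L) {
    for (i in seq_len(m - 1L)) {
      pair <- outer(alpha[i, ], p[i + 1L, ] + beta[i + 1L, ], `+`) + a
      d_a <- d_a + exp(pair - logz)
    }
    obs <- table(factor(y[-m], levels = seq_len(t_n)),
                 factor(y[-1L], levels = seq_len(t_n)))
    d_a <- d_a - unclass(obs)
  }
  d_begin <- marg[1L, ]; d_begin[y[1L]] <- d_begin[y[1L]] - 1
  d_end <- marg[m, ]; d_end[y[m]] <- d_end[y[m]] - 1
  score <- crf_score(p, a, y) + begin[y[1L]] + endv[y[m]]
  list(nll = logz - score, d_p = d_p, d_a = d_a,
       d_begin = d_begin, d_end = d_end, log_z = logz)
}

# ---- user-facing encoder / emission operations --------------------------

#' Encode a composed-embedding sequence
#'
#' Runs the model's stacked bidirectional LSTM over one sequence of
#' composed embeddings and returns the concatenated forward/backward
#' hidden states per position (`M x 2*hidden`).  Dropout is applied only
#' when `train = TRUE`.
#'
#' @param model A [cwae_model()].
#' @param xbar `M x d_comp` matrix of composed embeddings.
#' @param train Logical; apply dropout noise.
#' @return `M x 2*hidden` matrix of hidden states.
#' @export
encode_sequence <- function(model, xbar, train = FALSE) {
  xbar <- as.matrix(xbar)
  if (nrow(xbar) < 1L) stop("empty sequence")
  cf <- model$config
  m <- nrow(xbar)
  idx <- matrix(seq_len(m), 1L)
  idx_rev <- matrix(rev(seq_len(m)), 1L)
  layer_in <- xbar
  for (l in seq_len(cf$num_layers)) {
    f <- lstm_forward(layer_in, idx, lstm_par(model$par, l, "f"),
                      cf$hidden, cache = FALSE)
    b <- lstm_forward(layer_in, idx_rev, lstm_par(model$par, l, "b"),
                      cf$hidden, cache = FALSE)
    layer_in <- cbind(f$h_out, b$h_out)
  }
  h <- layer_in
  if (train && cf$dropout > 0)
    h <- h * ((matrix(stats::runif(length(h)), nrow(h)) >= cf$dropout) /
                (1 - cf$dropout))
  h
}

#' Emission matrix from encoder states
#'
#' Projects hidden states to the label space; in softmax mode each row
#' is additionally normalized to a probability vector.
#'
#' @param model A [cwae_model()].
#' @param h `M x 2*hidden` matrix from [encode_sequence()].
#' @return `M x T` emission matrix.
#' @export
emissions <- function(model, h) {
  h <- as.matrix(h)
  if (ncol(h) != nrow(model$par$W_out))
    stop("hidden dimension mismatch with the label projection")
  logits <- addb(h %*% model$par$W_out, model$par$b_out)
  if (model$config$emission_mode == "softmax") softmax_rows(logits)
  else logits
}

#' Predict labels for sentences
#'
#' Deterministic (dropout disabled) Viterbi decoding of each sentence.
#' Unknown words and characters fall back to the unknown-token
#' embeddings fixed at model construction.
#'
#' @param model A [cwae_model()].
#' @param sentences List of [ner_sentence()]s (labels ignored).
#' @param batch_size Internal batch size for the forward pass.
#' @return The sentences with `labels` replaced by predictions.
#' @export
predict_sentences <- function(model, sentences, batch_size = 64L) {
  if (length(sentences) == 0L) return(list())
  out <- vector("list", length(sentences))
  cf <- model$config
  begin <- if (cf$boundary_transitions) model$par$A_begin else NULL
  endv <- if (cf$boundary_transitions) model$par$A_end else NULL
  for (start in seq(1L, length(sentences), by = batch_size)) {
    sel <- start:min(start + batch_size - 1L, length(sentences))
    chunk <- sentences[sel]
    chunk <- lapply(chunk, function(s) {
      s$labels <- rep("O", length(s$words)); s
    })
    batch <- prepare_batch(model, chunk)
    fw <- model_forward(model, batch, train = FALSE, cache = FALSE)
    for (s in seq_along(chunk)) {
      rows <- batch$idx[s, seq_len(batch$lens[s])]
      p_s <- fw$p[rows, , drop = FALSE]
      if (!is.null(begin)) p_s[1L, ] <- p_s[1L, ] + begin
      if (!is.null(endv)) p_s[nrow(p_s), ] <- p_s[nrow(p_s), ] + endv
      vit <- viterbi(p_s, model$par$A)
      sent <- sentences[[sel[s]]]
      sent$labels <- model$scheme$labels[vit$y]
      out[[sel[s]]] <- sent
    }
  }
  out
}

# ---- checkpointing ------------------------------------------------------

#' Save or load a model checkpoint
#'
#' The checkpoint is a versioned, self-describing archive containing
#' every parameter tensor plus the label scheme, vocabulary and
#' configuration.
#'
#' @param model A [cwae_model()].
#' @param path File path.
#' @return `path` (save) or the restored `cwae_model` (load).
#' @export
save_model <- function(model, path) {
  saveRDS(list(format = "cwaner-checkpoint", version = 1L,
               config = model$config, scheme = model$scheme,
               vocab = model$vocab, par = model$par,
               channels = model$channels), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "cwaner-checkpoint"))
    stop("not a cwaner checkpoint: ", path)
  if (obj$version > 1L)
    stop("checkpoint version ", obj$version, " is newer than this package")
  structure(list(config = obj$config, scheme = obj$scheme,
                 vocab = obj$vocab, par = obj$par,
                 channels = obj$channels),
            class = "cwae_model")
}
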