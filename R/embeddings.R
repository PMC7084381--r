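# Character-enhanced word embeddings (CWE) and embedding-table plumbing.

# Run expr with a private RNG stream, restoring the caller's state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Create an embedding table
#'
#' A dense `id -> vector` map aligned to a vocabulary index.  Row order
#' follows the 0-based ids of the index (row `i` holds id `i - 1`); the
#' PAD row is identically zero and is never updated by training.
#'
#' @param index Named 0-based id map (see [build_vocab()]).
#' @param dim Embedding dimension.
#' @param kind `"word"` or `"character"`.
#' @param init `"uniform"` draws each non-PAD row with
#'   [init_unregistered()]; `"zero"` leaves all rows zero.
#' @param seed Integer seed for the uniform initialization.
#' @param init_rule Passed to [init_unregistered()].
#' @return An object of class `embedding_table`: list with `kind`, `dim`
#'   and `vectors` (a matrix with token rownames).
#' @export
embedding_table <- function(index, dim, kind = c("word", "character"),
                            init = c("uniform", "zero"), seed = 1L,
                            init_rule = c("sqrt", "literal")) {
  kind <- match.arg(kind); init <- match.arg(init)
  vec <- matrix(0, nrow = length(index), ncol = dim,
                dimnames = list(names(index), NULL))
  if (init == "uniform") {
    with_seed(seed, {
      for (i in seq_along(index))
        if (names(index)[i] != pad_token())
          vec[i, ] <- init_unregistered(dim, kind, rule = init_rule)
    })
  }
  structure(list(kind = kind, dim = dim, vectors = vec),
            class = "embedding_table")
}

#' @export
print.embedding_table <- function(x, ...) {
  cat("<embedding_table> ", nrow(x$vectors), " ", x$kind, "s x ",
      x$dim, " dims\n", sep = "")
  invisible(x)
}

#' Random initialization for unregistered tokens
#'
#' Draws a vector uniformly from the symmetric interval
#' `[-sqrt(3/dim), +sqrt(3/dim)]` per component, the
#' variance-preserving uniform rule (each component then has variance
#' `1/dim`).  `rule = "literal"` instead uses the interval
#' `[-3/dim, +3/dim]`.
#'
#' @param dim Vector length.
#' @param kind `"word"` or `"character"` (informational).
#' @param rule `"sqrt"` (default) or `"literal"`.
#' @param seed Optional seed; when given the draw is reproducible and the
#'   caller's RNG state is untouched.
#' @return Numeric vector of length `dim`.
#' @export
init_unregistered <- function(dim, kind = c("word", "character"),
                              rule = c("sqrt", "literal"), seed = NULL) {
  match.arg(kind); rule <- match.arg(rule)
  stopifnot(dim >= 1L)
  bound <- if (rule == "sqrt") sqrt(3 / dim) else 3 / dim
  if (is.null(seed)) stats::runif(dim, -bound, bound)
  else with_seed(seed, stats::runif(dim, -bound, bound))
}

#' CWE context-word representation
#'
#' A context word is represented jointly by its word vector and the mean
#' of its character vectors: `x = (w + mean(c_1..c_N)) / 2`.  Requires
#' the word and character tables to share one dimension.
#'
#' @param word_id 0-based word id.
#' @param char_ids Integer vector of 0-based character ids (no PAD),
#'   length `N >= 1`.
#' @param word_table,char_table [embedding_table()]s with equal `dim`.
#' @return Numeric vector of length `word_table$dim`.
#' @export
context_vector <- function(word_id, char_ids, word_table, char_table) {
  if (word_table$dim != char_table$dim)
    stop("CWE requires d_char == d_word (got ", char_table$dim, " vs ",
         word_table$dim, ")")
  if (length(char_ids) < 1L) stop("a word needs at least one character")
  w <- word_table$vectors[word_id + 1L, ]
  cm <- char_table$vectors[char_ids + 1L, , drop = FALSE]
  0.5 * (w + colMeans(cm))
}

#' CWE training configuration
#'
#' @param window Context half-width `K` (tokens on each side).
#' @param dim_word,dim_char Embedding dimensions; CWE requires them equal.
#' @param epochs Passes over the corpus.
#' @param negative_samples Negatives per positive in the sampled
#'   objective.
#' @param lr Fixed learning rate.
#' @param seed RNG seed; training is deterministic given the seed.
#' @return A list of class `cwe_config`.
#' @export
cwe_config <- function(window = 2L, dim_word = 100L, dim_char = 100L,
                       epochs = 5L, negative_samples = 5L, lr = 0.05,
                       seed = 1L) {
  stopifnot(window >= 1L, dim_word >= 1L, dim_char >= 1L, epochs >= 0L,
            negative_samples >= 1L, lr > 0)
  if (dim_word != dim_char)
    stop("CWE requires d_char == d_word (their vectors are added)")
  structure(list(window = as.integer(window), dim_word = as.integer(dim_word),
                 dim_char = as.integer(dim_char), epochs = as.integer(epochs),
                 negative_samples = as.integer(negative_samples),
                 lr = lr, seed = as.integer(seed)),
            class = "cwe_config")
}

#' Train character-enhanced word embeddings
#'
#' CBOW-style objective: predict each target word from the average of the
#' CWE context representations ([context_vector()]) in a window of `K`
#' tokens on each side.  The full softmax is replaced by negative
#' sampling (unigram distribution raised to 3/4).  Gradients flow into
#' the context word vectors and, split equally, into their character
#' vectors; the PAD vector is never touched.
#'
#' @param corpus List of [ner_sentence()] objects.
#' @param cfg A [cwe_config()].
#' @param vocab Optional [build_vocab()] result; built from `corpus`
#'   when `NULL`.
#' @return List with `word` and `char` [embedding_table()]s and
#'   `objective`, the per-epoch mean sampled log-likelihood.
#' @export
cwe_train <- function(corpus, cfg = cwe_config(), vocab = NULL) {
  if (length(corpus) == 0L) stop("empty corpus")
  if (max(vapply(corpus, function(s) length(s$words), integer(1))) <
      2L * cfg$window + 1L && length(corpus) == 1L)
    stop("corpus smaller than the context window")
  if (is.null(vocab)) vocab <- build_vocab(corpus)
  d <- cfg$dim_word
  wt <- embedding_table(vocab$word_index, d, "word", seed = cfg$seed)
  ct <- embedding_table(vocab$char_index, d, "character",
                        seed = cfg$seed + 1L)
  if (cfg$epochs == 0L)
    return(list(word = wt, char = ct, objective = numeric()))

  W <- wt$vectors; C <- ct$vectors
  O <- matrix(0, nrow(W), d)            # output (prediction) word matrix
  # integer encoding of the corpus
  sent_ids <- lapply(corpus, function(s) vocab_lookup(s$words,
                                                      vocab$word_index))
  # char ids per word id (words of the vocabulary only)
  word_chars <- vector("list", nrow(W))
  for (w in names(vocab$word_index)) {
    if (w %in% c(pad_token(), unk_token())) next
    word_chars[[vocab$word_index[[w]] + 1L]] <-
      vocab_lookup(strsplit(w, "")[[1L]], vocab$char_index) + 1L
  }
  # negative-sampling distribution over real words
  real <- which(vocab$word_count > 0L)
  neg_p <- vocab$word_count[real]^0.75
  neg_p <- neg_p / sum(neg_p)
  pad_row <- vocab$word_index[[pad_token()]] + 1L

  ctx_vec <- function(row) {
    ch <- word_chars[[row]]
    if (is.null(ch)) 0.5 * W[row, ]     # UNK has no characters
    else 0.5 * (W[row, ] + colMeans(C[ch, , drop = FALSE]))
  }

  objective <- numeric(cfg$epochs)
  with_seed(cfg$seed, {
    for (ep in seq_len(cfg$epochs)) {
      tot <- 0; nobs <- 0L
      for (ids in sent_ids) {
        rows <- ids + 1L
        n <- length(rows)
        for (i in seq_len(n)) {
          lo <- max(1L, i - cfg$window); hi <- min(n, i + cfg$window)
          ctx <- setdiff(lo:hi, i)
          if (!length(ctx)) next
          h <- rowMeans(vapply(rows[ctx], ctx_vec, numeric(d)))
          tgt <- rows[i]
          negs <- real[sample.int(length(real), cfg$negative_samples,
                                  replace = TRUE, prob = neg_p)]
          outs <- c(tgt, negs)
          lab <- c(1, rep(0, length(negs)))
          sc <- drop(O[outs, , drop = FALSE] %*% h)
          sig <- 1 / (1 + exp(-sc))
          g <- cfg$lr * (lab - sig)
          gh <- drop(crossprod(O[outs, , drop = FALSE], g))
          O[outs, ] <- O[outs, ] + outer(g, h)
          # distribute to context words and their characters
          gw <- gh * 0.5 / length(ctx)
          for (r in rows[ctx]) {
            if (r != pad_row) W[r, ] <- W[r, ] + gw
            ch <- word_chars[[r]]
            if (!is.null(ch))
              C[ch, ] <- sweep(C[ch, , drop = FALSE], 2L,
                               gw / length(ch), `+`)
          }
          tot <- tot + sum(log(pmax(ifelse(lab == 1, sig, 1 - sig),
                                    1e-12)))
          nobs <- nobs + 1L
        }
      }
      objective[ep] <- tot / max(nobs, 1L)
    }
  })
  wt$vectors <- W; ct$vectors <- C
  list(word = wt, char = ct, objective = objective)
}

#' Save / load embeddings in word2vec text format
#'
#' First line `count dim`, then one `token v1 ... vd` line per token.
#' `load_embeddings(save_embeddings(t, f))` reproduces `t` within 1e-6.
#'
#' @param table An [embedding_table()].
#' @param path File path.
#' @param kind Table kind to attach on load.
#' @param expect_dim Optional dimension check on load.
#' @return `path` (save) or an `embedding_table` (load).
#' @export
save_embeddings <- function(table, path) {
  v <- table$vectors
  lines <- c(paste(nrow(v), ncol(v)),
             paste(rownames(v),
                   apply(v, 1L, function(r)
                     paste(sprintf("%.8g", r), collapse = " "))))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(enc2utf8(lines), con, useBytes = TRUE)
  invisible(path)
}

#' @rdname save_embeddings
#' @export
load_embeddings <- function(path, kind = c("word", "character"),
                            expect_dim = NULL) {
  kind <- match.arg(kind)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  hdr <- strsplit(trimws(lines[1L]), " ", fixed = TRUE)[[1L]]
  if (length(hdr) != 2L || anyNA(suppressWarnings(as.integer(hdr))))
    stop("malformed word2vec header")
  n <- as.integer(hdr[1L]); d <- as.integer(hdr[2L])
  if (!is.null(expect_dim) && d != expect_dim)
    stop("embedding dimension ", d, " does not match configured ",
         expect_dim)
  body <- lines[-1L]
  body <- body[nzchar(body)]
  if (length(body) != n)
    stop("header declares ", n, " rows but file has ", length(body))
  vec <- matrix(0, n, d)
  toks <- character(n)
  for (i in seq_len(n)) {
    parts <- strsplit(body[i], " ", fixed = TRUE)[[1L]]
    if (length(parts) != d + 1L)
      stop("line ", i + 1L, ": expected ", d + 1L, " fields")
    toks[i] <- parts[1L]
    vec[i, ] <- as.numeric(parts[-1L])
  }
  rownames(vec) <- toks
  structure(list(kind = kind, dim = d, vectors = vec),
            class = "embedding_table")
}
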