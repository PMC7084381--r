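# Character CNN and the character/word attention gate.

act_fun <- function(name) {
  switch(name,
         relu = function(x) pmax(x, 0),
         tanh = tanh,
         identity = function(x) x,
         stop("unknown activation: ", name))
}

act_grad <- function(name, pre, post) {
  switch(name,
         relu = (pre > 0) * 1,
         tanh = 1 - post^2,
         identity = array(1, dim(as.matrix(pre))),
         stop("unknown activation: ", name))
}

#' Create a convolutional filter bank
#'
#' Filters of several window widths slide (step 1) over a word's
#' character-vector rows; each filter's responses are max-pooled to one
#' value, and all channels concatenate to the character-based embedding.
#' The total channel budget is split as evenly as possible across widths
#' (200 over widths 2,3,4 gives 67/67/66).
#'
#' @param widths Integer vector of filter window widths (default 2,3,4).
#' @param out_channels Total output channels (default 200).
#' @param d_char Character embedding dimension (default 100).
#' @param activation `"relu"` (default), `"tanh"` or `"identity"`.
#' @param seed Seed for weight initialization.
#' @return An object of class `filter_bank`: per-width weight matrices
#'   `W` (`width * d_char` by `channels`) and bias vectors `b`.
#' @export
filter_bank <- function(widths = c(2L, 3L, 4L), out_channels = 200L,
                        d_char = 100L, activation = "relu", seed = 1L) {
  widths <- sort(as.integer(widths))
  stopifnot(length(widths) >= 1L, all(widths >= 1L), out_channels >= 1L)
  k <- rep(out_channels %/% length(widths), length(widths))
  extra <- out_channels %% length(widths)
  if (extra > 0L) k[seq_len(extra)] <- k[seq_len(extra)] + 1L
  bank <- with_seed(seed, lapply(seq_along(widths), function(i) {
    fan_in <- widths[i] * d_char
    bound <- sqrt(6 / (fan_in + k[i]))
    list(width = widths[i],
         W = matrix(stats::runif(fan_in * k[i], -bound, bound),
                    fan_in, k[i]),
         b = rep(0, k[i]))
  }))
  structure(list(widths = widths, channels = k, d_char = d_char,
                 activation = activation, filters = bank),
            class = "filter_bank")
}

# Window positions admitted to the max-pool.  A word of n_real
# characters padded for filter width s canonically spans max(n_real, s)
# rows, giving max(n_real - s + 1, 1) windows: every window that fits
# inside the real characters, or the single PAD-completed window when
# the word is shorter than the filter.  Windows further into the
# padding are masked, which makes the pooled features invariant to how
# much padding the batch layout appends.
valid_positions <- function(n_real, width, w_l) {
  n_pos <- w_l - width + 1L
  seq_len(n_pos) <= max(n_real - width + 1L, 1L)
}

#' Character-based embedding of one word by CNN
#'
#' For each filter width `s`: slide a width-`s` window over the
#' character rows with step 1, apply the activation, max-pool over
#' window positions, and concatenate all channels.  The pool covers the
#' windows lying within the word's real characters (plus the single
#' PAD-completed window when the word is shorter than the filter), so
#' appending PAD rows never changes the result; words shorter than a
#' width are PAD-extended as needed, never an error.
#'
#' @param char_mat `W_l x d_char` matrix of character vectors (rows in
#'   word order, PAD rows zero), at least one non-PAD row.
#' @param bank A [filter_bank()].
#' @param n_real Number of non-PAD rows; defaults to the count of
#'   non-zero rows.
#' @return Numeric vector of length `sum(bank$channels)`.
#' @export
char_cnn <- function(char_mat, bank, n_real = NULL) {
  char_mat <- as.matrix(char_mat)
  if (ncol(char_mat) != bank$d_char)
    stop("character dimension ", ncol(char_mat), " does not match bank (",
         bank$d_char, ")")
  if (is.null(n_real)) {
    nz <- rowSums(char_mat != 0) > 0
    n_real <- if (any(nz)) max(which(nz)) else 1L
  }
  w_l <- max(nrow(char_mat), max(bank$widths))
  if (nrow(char_mat) < w_l)
    char_mat <- rbind(char_mat,
                      matrix(0, w_l - nrow(char_mat), ncol(char_mat)))
  f <- act_fun(bank$activation)
  out <- lapply(bank$filters, function(fl) {
    s <- fl$width
    pos <- which(valid_positions(n_real, s, w_l))
    scores <- vapply(pos, function(p) {
      win <- as.vector(t(char_mat[p:(p + s - 1L), , drop = FALSE]))
      f(drop(win %*% fl$W) + fl$b)
    }, numeric(ncol(fl$W)))
    if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1L)
    apply(scores, 1L, max)
  })
  unlist(out, use.names = FALSE)
}

#' Create attention-gate parameters
#'
#' @param d_out Dimension of the composed embedding (default 200).
#' @param d_word Dimension of the (projected) word embedding entering the
#'   gate; must equal `d_out`.
#' @param seed Seed for initialization.
#' @return An object of class `gate_params` with `W_g`
#'   (`2*d_out x d_out`), `b_g`, `U` (`d_out x d_out`), `b_z`.
#' @export
gate_params <- function(d_out = 200L, d_word = d_out, seed = 1L) {
  if (d_word != d_out)
    stop("gate requires the word embedding projected to d_out")
  with_seed(seed, {
    b1 <- sqrt(6 / (3 * d_out))
    b2 <- sqrt(6 / (2 * d_out))
    structure(list(
      W_g = matrix(stats::runif(2 * d_out * d_out, -b1, b1),
                   2L * d_out, d_out),
      b_g = rep(0, d_out),
      U = matrix(stats::runif(d_out * d_out, -b2, b2), d_out, d_out),
      b_z = rep(0, d_out),
      d_out = as.integer(d_out)), class = "gate_params")
  })
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Mix word and character embeddings through the attention gate
#'
#' Computes `O_g = tanh(W_g' [X; C] + b_g)`, the per-dimension gate
#' `z = sigmoid(U' O_g + b_z)` and the composed embedding
#' `Xbar = z * X + (1 - z) * C` (all elementwise).  Since `z` lies in
#' (0, 1), each component of `Xbar` is a strict convex combination of
#' the corresponding components of `X` and `C`.
#'
#' @param x Word vector (projected to `d_out`), or a matrix with one row
#'   per token.
#' @param c_i Character-based embedding(s), same shape as `x`.
#' @param params A [gate_params()].
#' @return List with `xbar` (composed embedding) and `z` (gate values),
#'   shaped like the input.
#' @export
attention_gate <- function(x, c_i, params) {
  vec_in <- is.null(dim(x))
  if (vec_in) {
    x <- matrix(x, nrow = 1L)
    c_i <- matrix(c_i, nrow = 1L)
  }
  if (!all(dim(x) == dim(c_i)) || ncol(x) != params$d_out)
    stop("gate shape mismatch: X and C must both be d_out = ",
         params$d_out)
  og <- tanh(cbind(x, c_i) %*% params$W_g +
               rep(params$b_g, each = nrow(x)))
  z <- sigmoid(og %*% params$U + rep(params$b_z, each = nrow(x)))
  xbar <- z * x + (1 - z) * c_i
  if (vec_in) list(xbar = drop(xbar), z = drop(z))
  else list(xbar = xbar, z = z)
}
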