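# Linear-chain CRF: scoring, exact inference, gradients.
#
# Scores follow the chain rule without begin/end boundary terms:
#   s(X, y) = sum_{i=1}^{M-1} A[y_i, y_{i+1}] + sum_{i=1}^{M} P[i, y_i]
# where P is the M x T emission matrix and A the T x T transition
# matrix.  Label ids are 1-based in R.

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

check_crf_args <- function(p, a, y = NULL) {
  p <- as.matrix(p)
  t_n <- ncol(p)
  stopifnot(nrow(a) == t_n, ncol(a) == t_n, all(is.finite(a)))
  if (!is.null(y)) {
    if (length(y) != nrow(p)) stop("|y| must equal the sentence length M")
    if (any(y < 1L | y > t_n)) stop("label id outside 1..T")
  }
  p
}

#' CRF path score
#'
#' @param p `M x T` emission matrix.
#' @param a `T x T` transition matrix (`a[y, y']` scores moving from
#'   label `y` to `y'`).
#' @param y Integer label sequence (1-based ids, length `M`).
#' @return The scalar path score.
#' @export
crf_score <- function(p, a, y) {
  p <- check_crf_args(p, a, y)
  m <- nrow(p)
  trans <- if (m > 1L) sum(a[cbind(y[-m], y[-1L])]) else 0
  trans + sum(p[cbind(seq_len(m), y)])
}

#' Log-partition function (forward algorithm)
#'
#' Computes `log sum_y exp(s(X, y))` over all `T^M` label sequences by
#' dynamic programming in `O(M T^2)` with log-sum-exp stabilization.
#'
#' @inheritParams crf_score
#' @return The scalar log-partition value.
#' @export
log_partition <- function(p, a) {
  p <- check_crf_args(p, a)
  alpha <- p[1L, ]
  for (i in seq_len(nrow(p))[-1L]) {
    alpha <- apply(alpha + a, 2L, logsumexp) + p[i, ]
  }
  logsumexp(alpha)
}

#' Log-probability of a label sequence
#'
#' `crf_score(p, a, y) - log_partition(p, a)`; the exponentials over all
#' sequences sum to one.
#'
#' @inheritParams crf_score
#' @return Scalar log-probability (non-positive up to float error).
#' @export
sequence_log_prob <- function(p, a, y) {
  crf_score(p, a, y) - log_partition(p, a)
}

#' Viterbi decoding
#'
#' Returns the highest-scoring label sequence.  Ties are broken toward
#' the smallest label id at every backtrack step.
#'
#' @inheritParams crf_score
#' @return List with `y` (integer sequence) and `score`.
#' @export
viterbi <- function(p, a) {
  p <- check_crf_args(p, a)
  m <- nrow(p); t_n <- ncol(p)
  delta <- p[1L, ]
  back <- matrix(0L, m, t_n)
  for (i in seq_len(m)[-1L]) {
    cand <- delta + a                      # cand[y_prev, y]
    back[i, ] <- apply(cand, 2L, which.max)
    delta <- cand[cbind(back[i, ], seq_len(t_n))] + p[i, ]
  }
  y <- integer(m)
  y[m] <- which.max(delta)
  if (m > 1L) for (i in m:2L) y[i - 1L] <- back[i, y[i]]
  list(y = y, score = unname(delta[y[m]]))
}

#' Exhaustive best sequence (test oracle)
#'
#' Enumerates all `T^M` label sequences and returns the maximizer under
#' the same tie-break rule as [viterbi()] (among equal-scoring
#' sequences, the one smallest when compared from the last position
#' backwards).
#'
#' @inheritParams crf_score
#' @return List with `y` and `score`.
#' @export
brute_force_best <- function(p, a) {
  p <- check_crf_args(p, a)
  m <- nrow(p); t_n <- ncol(p)
  if (t_n^m > 1e6) stop("instance too large to enumerate (T^M > 1e6)")
  grid <- as.matrix(expand.grid(rep(list(seq_len(t_n)), m)))
  # expand.grid varies the first column fastest, so row order is
  # lexicographic when read from the last position backwards; the first
  # strict maximum therefore matches Viterbi's tie-break.
  best <- NULL; best_score <- -Inf
  for (r in seq_len(nrow(grid))) {
    y <- grid[r, ]
    s <- crf_score(p, a, y)
    if (s > best_score) { best_score <- s; best <- y }
  }
  list(y = unname(as.integer(best)), score = best_score)
}

# Forward-backward marginals and the gradient of the negative
# log-likelihood -log p(y | X) with respect to P and A.  Uses the
# scaled (normalized) forward-backward recursion so the inner loop is
# plain matrix-vector arithmetic; per-row emission max-shifts keep the
# exponentials bounded in logit mode.
crf_grads <- function(p, a, y) {
  p <- check_crf_args(p, a, y)
  m <- nrow(p); t_n <- ncol(p)
  shift <- apply(p, 1L, max)
  e <- exp(p - shift)                    # shifted emissions
  ea <- exp(a)
  ahat <- matrix(0, m, t_n)              # scaled alphas (rows sum to 1)
  cs <- numeric(m)                       # per-step scaling factors
  u <- e[1L, ]
  cs[1L] <- sum(u)
  ahat[1L, ] <- u / cs[1L]
  for (i in seq_len(m)[-1L]) {
    u <- drop(ahat[i - 1L, ] %*% ea) * e[i, ]
    cs[i] <- sum(u)
    ahat[i, ] <- u / cs[i]
  }
  logz <- sum(log(cs)) + sum(shift)
  bhat <- matrix(0, m, t_n)              # scaled betas
  bhat[m, ] <- 1
  if (m > 1L) for (i in (m - 1L):1L)
    bhat[i, ] <- drop(ea %*% (e[i + 1L, ] * bhat[i + 1L, ])) / cs[i + 1L]
  d_p <- ahat * bhat                     # unary marginals
  d_p[cbind(seq_len(m), y)] <- d_p[cbind(seq_len(m), y)] - 1
  d_a <- matrix(0, t_n, t_n)
  if (m > 1L) {
    v <- e[-1L, , drop = FALSE] * bhat[-1L, , drop = FALSE] / cs[-1L]
    d_a <- ea * crossprod(ahat[-m, , drop = FALSE], v)
    obs <- tabulate((y[-1L] - 1L) * t_n + y[-m], nbins = t_n * t_n)
    d_a <- d_a - matrix(obs, t_n, t_n)
  }
  list(nll = logz - crf_score(p, a, y), d_p = d_p, d_a = d_a,
       log_z = logz)
}
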