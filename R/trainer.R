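# Training loop: mini-batching, Adam, learning-rate decay, gradient
# clipping, per-epoch evaluation.

#' Training configuration
#'
#' Defaults follow the published recipe: mini-batches of 20 sentences,
#' Adam with initial learning rate 0.001 multiplied by 0.9 after every
#' epoch, global-norm gradient clipping at 5.0, dropout 0.5, 35 epochs.
#'
#' @param batch_size Sentences per mini-batch.
#' @param epochs Number of passes over the training set.
#' @param lr Initial learning rate.
#' @param lr_decay Multiplicative decay applied per epoch
#'   (`lr * lr_decay^epoch`).
#' @param grad_clip Global-norm clipping threshold.
#' @param optimizer `"adam"` (default moments 0.9/0.999) or `"sgd"`.
#' @param keep_best Track and restore the best-on-dev checkpoint (off by
#'   default; the recipe trains a fixed number of epochs).
#' @param seed RNG seed controlling shuffling and dropout.
#' @return A list of class `train_config`.
#' @export
train_config <- function(batch_size = 20L, epochs = 35L, lr = 0.001,
                         lr_decay = 0.9, grad_clip = 5.0,
                         optimizer = c("adam", "sgd"),
                         keep_best = FALSE, seed = 1L) {
  optimizer <- match.arg(optimizer)
  stopifnot(batch_size >= 1L, epochs >= 0L, lr > 0, lr_decay > 0,
            grad_clip > 0)
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), lr = lr,
                 lr_decay = lr_decay, grad_clip = grad_clip,
                 optimizer = optimizer, keep_best = isTRUE(keep_best),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Split sentences into shuffled mini-batches
#'
#' @param sentences Non-empty list of sentences.
#' @param batch_size Batch size; the last short batch is kept.
#' @param shuffle Shuffle the order (uses the current RNG stream).
#' @param seed Optional seed; when given, shuffling is reproducible and
#'   the caller's RNG state is untouched.
#' @return List of lists of sentences.
#' @export
make_batches <- function(sentences, batch_size, shuffle = TRUE,
                         seed = NULL) {
  n <- length(sentences)
  if (n == 0L) stop("no sentences to batch")
  ord <- if (!shuffle) seq_len(n)
         else if (is.null(seed)) sample.int(n)
         else with_seed(seed, sample.int(n))
  unname(split(sentences[ord], ceiling(seq_len(n) / batch_size)))
}

global_norm <- function(grads)
  sqrt(sum(vapply(grads, function(g) sum(g * g), numeric(1))))

clip_global <- function(grads, max_norm) {
  nrm <- global_norm(grads)
  if (nrm > max_norm) grads <- lapply(grads, function(g)
    g * (max_norm / nrm))
  list(grads = grads, norm = min(nrm, max_norm), raw_norm = nrm)
}

adam_init <- function(par) list(
  m = zero_like(par), v = zero_like(par), t = 0L)

#' Train a tagger
#'
#' Mini-batch training of the full model: per epoch, the training set is
#' reshuffled, character padding is applied per batch, gradients of the
#' mean CRF negative log-likelihood are clipped to a global norm of
#' `grad_clip` and applied with Adam at `lr * lr_decay^epoch`.  After
#' each epoch the model is scored on `dev_set` with strict entity-level
#' metrics.  Fully reproducible given `cfg$seed`.
#'
#' @param model A [cwae_model()].
#' @param train_set,dev_set Lists of labelled [ner_sentence()]s.
#' @param cfg A [train_config()].
#' @param verbose Emit one log line per epoch
#'   (`epoch, lr, loss, dev_P, dev_R, dev_F1`).
#' @return List with the trained `model` and `history`, a `data.frame`
#'   with one row per epoch: `epoch`, `lr`, `loss`, `dev_p`, `dev_r`,
#'   `dev_f1`, `max_grad_norm` (post-clip maximum over the epoch's
#'   steps).
#' @export
train <- function(model, train_set, dev_set, cfg = train_config(),
                  verbose = TRUE) {
  if (length(train_set) == 0L) stop("empty training set")
  hist <- data.frame(epoch = integer(), lr = numeric(), loss = numeric(),
                     dev_p = numeric(), dev_r = numeric(),
                     dev_f1 = numeric(), max_grad_norm = numeric())
  if (cfg$epochs == 0L) return(list(model = model, history = hist))
  # the Adam kernel updates parameters in place, so give this run its
  # own private copy of every tensor
  model$par <- lapply(model$par, function(x) x + 0)
  state <- if (cfg$optimizer == "adam") adam_init(model$par) else NULL
  best <- NULL
  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs)) {
      lr_t <- cfg$lr * cfg$lr_decay^(epoch - 1L)
      batches <- make_batches(train_set, cfg$batch_size)
      ep_loss <- 0; max_nrm <- 0
      for (b in batches) {
        lg <- model_loss_grads(model, b, train = TRUE)
        if (!is.finite(lg$loss))
          stop("training diverged: non-finite loss at epoch ", epoch)
        cl <- clip_global(lg$grads, cfg$grad_clip)
        max_nrm <- max(max_nrm, cl$norm)
        if (cfg$optimizer == "adam") {
          state$t <- state$t + 1L
          .adam_update_cpp(model$par, cl$grads[names(model$par)],
                           state$m, state$v, lr_t, 0.9, 0.999, 1e-8,
                           state$t)
        } else {
          for (nm in names(model$par))
            model$par[[nm]] <- model$par[[nm]] - lr_t * cl$grads[[nm]]
        }
        # PAD embedding rows receive zero gradients, so both optimizers
        # leave them at exactly zero
        ep_loss <- ep_loss + lg$loss * length(b)
      }
      ep_loss <- ep_loss / length(train_set)
      dev <- c(p = NA_real_, r = NA_real_, f1 = NA_real_)
      if (length(dev_set)) {
        pred <- predict_sentences(model, dev_set)
        rep_ <- evaluate_corpus(dev_set, pred, model$scheme)
        dev <- c(p = rep_$overall$P, r = rep_$overall$R,
                 f1 = rep_$overall$F1)
      }
      hist[epoch, ] <- list(epoch, lr_t, ep_loss, dev[["p"]], dev[["r"]],
                            dev[["f1"]], max_nrm)
      if (verbose)
        message(sprintf(
          "epoch %d, lr %.6g, loss %.4f, dev_P %.2f, dev_R %.2f, dev_F1 %.2f",
          epoch, lr_t, ep_loss, dev[["p"]], dev[["r"]], dev[["f1"]]))
      if (cfg$keep_best && length(dev_set) &&
          (is.null(best) || dev[["f1"]] > best$f1))
        best <- list(f1 = dev[["f1"]],
                     par = lapply(model$par, function(x) x + 0))
    }
  })
  if (cfg$keep_best && !is.null(best)) model$par <- best$par
  list(model = model, history = hist)
}
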