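test_that("make_batches shuffles reproducibly and keeps the short tail", {
  sents <- replicate(45, ner_sentence("x"), simplify = FALSE)
  b <- make_batches(sents, 20, seed = 5)
  expect_equal(lengths(b), c(20L, 20L, 5L))
  expect_identical(make_batches(sents, 20, seed = 5), b)
  expect_error(make_batches(list(), 20), "no sentences")
})

test_that("per-batch character padding uses the batch maximum", {
  s <- ner_sentence(c("a", "bb", "ccc", "dddd"))
  model <- tiny_model()
  batch <- cwaner:::prepare_batch(model, list(s))
  expect_equal(batch$w_l, 4L)
  expect_equal(batch$n_real, 1:4)
  # all-short batch still covers the widest filter
  b2 <- cwaner:::prepare_batch(model, list(ner_sentence(c("a", "bb"))))
  expect_equal(b2$w_l, max(model$config$filter_widths))
})

test_that("learning rate decays by 0.9 per epoch from 0.001", {
  sents <- tiny_sentences()
  model <- tiny_model()
  fit <- train(model, sents, list(),
               train_config(batch_size = 3, epochs = 3, seed = 2),
               verbose = FALSE)
  expect_equal(fit$history$lr, 0.001 * 0.9^(0:2))
  expect_equal(fit$history$epoch, 1:3)
  # zero epochs: untouched model, empty history
  fit0 <- train(model, sents, list(),
                train_config(epochs = 0, seed = 2), verbose = FALSE)
  expect_equal(fit0$model$par, model$par)
  expect_equal(nrow(fit0$history), 0L)
})

test_that("gradient global norm never exceeds the clip threshold", {
  model <- tiny_model()
  fit <- train(model, tiny_sentences(), list(),
               train_config(batch_size = 2, epochs = 3, grad_clip = 0.5,
                            seed = 4), verbose = FALSE)
  expect_true(all(fit$history$max_grad_norm <= 0.5 + 1e-6))
  # clip_global rescales to exactly the threshold
  g <- list(a = matrix(3, 2, 2), b = rep(4, 3))
  cl <- cwaner:::clip_global(g, 1)
  expect_equal(cwaner:::global_norm(cl$grads), 1, tolerance = 1e-12)
  small <- cwaner:::clip_global(list(a = 0.1), 5)
  expect_equal(small$grads$a, 0.1)
})

test_that("identical seeds reproduce training exactly", {
  sents <- tiny_sentences()
  cfg <- train_config(batch_size = 2, epochs = 3, seed = 7)
  f1 <- train(tiny_model(dropout = 0.3), sents, sents, cfg,
              verbose = FALSE)
  f2 <- train(tiny_model(dropout = 0.3), sents, sents, cfg,
              verbose = FALSE)
  expect_identical(f1$history, f2$history)
  expect_equal(f1$model$par, f2$model$par)
  f3 <- train(tiny_model(dropout = 0.3), sents, sents,
              train_config(batch_size = 2, epochs = 3, seed = 8),
              verbose = FALSE)
  expect_false(identical(f1$history$loss, f3$history$loss))
})

test_that("training does not mutate the caller's model object", {
  model <- tiny_model()
  snapshot <- lapply(model$par, function(x) x + 0)
  invisible(train(model, tiny_sentences(), list(),
                  train_config(batch_size = 3, epochs = 2, seed = 1),
                  verbose = FALSE))
  expect_equal(model$par, snapshot)
})

test_that("PAD embedding rows stay exactly zero through training", {
  fit <- train(tiny_model(), tiny_sentences(), list(),
               train_config(batch_size = 2, epochs = 4, seed = 3),
               verbose = FALSE)
  expect_equal(unname(fit$model$par$E_w[1, ]),
               rep(0, ncol(fit$model$par$E_w)))
  expect_equal(unname(fit$model$par$E_c[1, ]),
               rep(0, ncol(fit$model$par$E_c)))
})

test_that("a tiny corpus is memorized to near-zero loss", {
  sents <- list(
    ner_sentence(c("aa", "bb"), c("B-disease", "O")),
    ner_sentence(c("cc", "aa"), c("O", "B-disease")),
    ner_sentence(c("dd", "ee"), c("B-drug", "I-drug")),
    ner_sentence(c("bb", "dd", "ee"), c("O", "B-drug", "I-drug")),
    ner_sentence(c("cc", "bb"), c("O", "O")))
  # raw-logit emissions: softmax-normalized emissions bound the
  # per-token score gap at 1, putting a positive floor under the NLL,
  # so the capacity check uses the unbounded wiring
  model <- cwae_model(build_vocab(sents), tiny_scheme(),
                      cwae_config(d_word = 12, d_char = 8,
                                  filter_widths = c(2), cnn_output = 8,
                                  d_comp = 8, hidden = 12,
                                  num_layers = 1, dropout = 0,
                                  emission_mode = "logit"),
                      seed = 5)
  fit <- train(model, sents, list(),
               train_config(batch_size = 5, epochs = 200, lr = 0.01,
                            lr_decay = 1, seed = 6), verbose = FALSE)
  expect_lt(fit$history$loss[200], 0.05)
  # converged model reproduces the training labels exactly
  pred <- predict_sentences(fit$model, sents)
  expect_equal(lapply(pred, `[[`, "labels"),
               lapply(sents, `[[`, "labels"))
})

test_that("prediction is deterministic and legal on unknown input", {
  model <- tiny_model(dropout = 0.5)
  s <- list(ner_sentence("zzz"))         # fully out-of-vocabulary
  p1 <- predict_sentences(model, s)
  p2 <- predict_sentences(model, s)
  expect_identical(p1, p2)
  expect_length(p1[[1]]$labels, 1L)
  expect_true(p1[[1]]$labels %in% model$scheme$labels)
  expect_identical(predict_sentences(model, list()), list())
})

test_that("training aborts with a diagnostic on divergence", {
  model <- tiny_model()
  model$par$W_out[] <- NaN
  expect_error(train(model, tiny_sentences(), list(),
                     train_config(epochs = 1, seed = 1),
                     verbose = FALSE),
               "diverged")
})
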