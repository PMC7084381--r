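test_that("crf_score follows the chain rule without boundary terms", {
  p <- matrix(c(1, 2, 3, 4), 2, byrow = TRUE)
  a <- matrix(c(0.5, 0.25, -0.5, 0), 2)
  expect_equal(crf_score(p, a, c(2, 1)), 2 + 3 + 0.25)
  # zero transitions reduce to the sum of emissions
  expect_equal(crf_score(p, 0 * a, c(1, 2)), 1 + 4)
  # single token: no transition term
  expect_equal(crf_score(p[1, , drop = FALSE], a, 2L), 2)
  expect_error(crf_score(p, a, c(1, 3)), "outside")
})

test_that("log_partition matches closed forms and enumeration", {
  # uniform case: T^M equal terms of score 0
  expect_equal(log_partition(matrix(0, 3, 4), matrix(0, 4, 4)),
               3 * log(4))
  # M = 1: logsumexp of the single emission row
  p1 <- matrix(c(0.3, -1, 2), 1)
  expect_equal(log_partition(p1, matrix(0, 3, 3)), log(sum(exp(p1))))
  set.seed(17)
  p <- matrix(rnorm(4 * 5), 4); a <- matrix(rnorm(25), 5)
  grid <- as.matrix(expand.grid(rep(list(1:5), 4)))
  brute <- log(sum(exp(apply(grid, 1, function(y) crf_score(p, a, y)))))
  expect_equal(log_partition(p, a), brute, tolerance = 1e-8)
})

test_that("sequence probabilities normalize and rank the argmax first", {
  # uniform case: every sequence has probability T^-M
  expect_equal(sequence_log_prob(matrix(0, 3, 4), matrix(0, 4, 4),
                                 c(2, 1, 4)), -3 * log(4))
  set.seed(19)
  p <- matrix(rnorm(9), 3); a <- matrix(rnorm(16), 4)
  p <- cbind(p, rnorm(3))                # M = 3, T = 4
  grid <- as.matrix(expand.grid(rep(list(1:4), 3)))
  lps <- apply(grid, 1, function(y) sequence_log_prob(p, a, y))
  expect_equal(sum(exp(lps)), 1, tolerance = 1e-8)
  best <- grid[which.max(lps), ]
  expect_equal(viterbi(p, a)$y, unname(as.integer(best)))
})

test_that("viterbi equals brute-force enumeration on random instances", {
  set.seed(23)
  for (i in 1:200) {
    m <- sample(1:6, 1); t_n <- sample(2:6, 1)
    p <- matrix(rnorm(m * t_n, sd = 2), m)
    a <- matrix(rnorm(t_n * t_n, sd = 2), t_n)
    v <- viterbi(p, a); b <- brute_force_best(p, a)
    expect_identical(v$y, b$y)
    expect_equal(v$score, b$score, tolerance = 1e-10)
  }
})

test_that("viterbi closed forms: decoupled chain and forced path", {
  set.seed(3)
  p <- matrix(rnorm(12), 4)
  expect_equal(viterbi(p, matrix(0, 3, 3))$y,
               unname(apply(p, 1, which.max)))
  # transitions allow only 1 -> 2 -> 3 -> 1 ...
  a <- matrix(-1e6, 3, 3)
  a[1, 2] <- a[2, 3] <- a[3, 1] <- 0
  pz <- matrix(0, 4, 3)
  pz[1, 1] <- 1                          # pin the start
  expect_equal(viterbi(pz, a)$y, c(1L, 2L, 3L, 1L))
  # uniform scores: tie-break picks label 1 everywhere
  expect_equal(viterbi(matrix(0, 3, 4), matrix(0, 4, 4))$y,
               rep(1L, 3))
  expect_equal(brute_force_best(matrix(0, 3, 4), matrix(0, 4, 4))$y,
               rep(1L, 3))
  expect_error(brute_force_best(matrix(0, 30, 4), matrix(0, 4, 4)),
               "too large")
})

test_that("adding a constant to an emission row shifts scores uniformly", {
  set.seed(29)
  p <- matrix(rnorm(15), 5); a <- matrix(rnorm(9), 3)
  p2 <- p; p2[3, ] <- p2[3, ] + 1.7
  y <- c(1, 3, 2, 2, 1)
  expect_equal(crf_score(p2, a, y), crf_score(p, a, y) + 1.7)
  expect_equal(sequence_log_prob(p2, a, y), sequence_log_prob(p, a, y))
  expect_identical(viterbi(p2, a)$y, viterbi(p, a)$y)
})

test_that("CRF analytic gradients match central differences", {
  set.seed(37)
  h <- 1e-6
  for (rep in 1:10) {
    m <- sample(2:5, 1); t_n <- sample(2:5, 1)
    p <- matrix(rnorm(m * t_n), m); a <- matrix(rnorm(t_n^2), t_n)
    y <- sample(t_n, m, replace = TRUE)
    gr <- cwaner:::crf_grads(p, a, y)
    expect_equal(gr$nll, -sequence_log_prob(p, a, y), tolerance = 1e-10)
    for (k in sample(length(p), 3)) {
      pp <- p; pp[k] <- pp[k] + h
      pm <- p; pm[k] <- pm[k] - h
      num <- (-sequence_log_prob(pp, a, y) +
                sequence_log_prob(pm, a, y)) / (2 * h)
      expect_equal(gr$d_p[k], num, tolerance = 1e-4)
    }
    for (k in sample(length(a), 3)) {
      ap <- a; ap[k] <- ap[k] + h
      am <- a; am[k] <- am[k] - h
      num <- (-sequence_log_prob(p, ap, y) +
                sequence_log_prob(p, am, y)) / (2 * h)
      expect_equal(gr$d_a[k], num, tolerance = 1e-4)
    }
  }
})

test_that("encoder output has the contracted shape and is deterministic", {
  model <- tiny_model()
  h <- model$config$hidden
  x1 <- matrix(rnorm(model$config$d_comp), 1)
  h1 <- encode_sequence(model, x1)
  expect_equal(dim(h1), c(1L, 2L * h))
  x <- matrix(rnorm(5 * model$config$d_comp), 5)
  expect_identical(encode_sequence(model, x), encode_sequence(model, x))
  expect_error(encode_sequence(model, x[0, , drop = FALSE]), "empty")
})

test_that("with tied weights the directions mirror under reversal", {
  # one bidirectional layer: stacking a second layer re-mixes the
  # direction blocks, so the mirror symmetry is a single-layer property
  model <- tiny_model(num_layers = 1)
  for (l in 1) for (w in c("Wx", "Wh", "b"))
    model$par[[paste0("lstm_", l, "_b_", w)]] <-
      model$par[[paste0("lstm_", l, "_f_", w)]]
  x <- matrix(rnorm(6 * model$config$d_comp), 6)
  h <- model$config$hidden
  fwd_cols <- 1:h; bwd_cols <- (h + 1):(2 * h)
  out <- encode_sequence(model, x)
  out_rev <- encode_sequence(model, x[6:1, , drop = FALSE])
  expect_equal(out_rev[6:1, fwd_cols], out[, bwd_cols])
  expect_equal(out_rev[6:1, bwd_cols], out[, fwd_cols])
})

test_that("emissions are a row-stochastic projection of hidden states", {
  model <- tiny_model(emission_mode = "softmax")
  x <- matrix(rnorm(4 * model$config$d_comp), 4)
  h <- encode_sequence(model, x)
  p <- emissions(model, h)
  expect_equal(dim(p), c(4L, model$scheme$T))
  expect_equal(rowSums(p), rep(1, 4), tolerance = 1e-6)
  # zero projection weights: uniform rows
  # logit mode returns the raw projection
  mraw <- tiny_model(emission_mode = "logit")
  mraw$par <- model$par
  expect_equal(emissions(mraw, h),
               cwaner:::addb(h %*% model$par$W_out, model$par$b_out))
  m0 <- model
  m0$par$W_out[] <- 0; m0$par$b_out[] <- 0
  expect_equal(unname(emissions(m0, h)),
               matrix(1 / model$scheme$T, 4, model$scheme$T))
  # a dominant logit saturates toward one-hot
  m1 <- m0
  m1$par$b_out[3] <- 50
  expect_equal(unname(emissions(m1, h)[, 3]), rep(1, 4),
               tolerance = 1e-12)
  expect_error(emissions(model, h[, 1:3]), "mismatch")
})

test_that("full-model gradients match central differences", {
  sents <- tiny_sentences()
  for (setup in list(list(act = "tanh", abl = FALSE, bnd = TRUE,
                          em = "softmax"),
                     list(act = "relu", abl = FALSE, bnd = FALSE,
                          em = "logit"),
                     list(act = "relu", abl = TRUE, bnd = FALSE,
                          em = "softmax"))) {
    model <- tiny_model(cnn_activation = setup$act,
                        char_ablation = setup$abl,
                        boundary_transitions = setup$bnd,
                        emission_mode = setup$em)
    lg <- model_loss_grads(model, sents, train = TRUE)
    h <- 1e-5
    set.seed(41)
    for (nm in names(model$par)) {
      par <- model$par[[nm]]
      ii <- sample(length(par), min(length(par), 6))
      if (nm %in% c("E_w", "E_c"))       # skip the frozen PAD row
        ii <- ii[(ii - 1) %% nrow(par) != 0]
      for (i in ii) {
        m2 <- model
        m2$par[[nm]][i] <- par[i] + h
        lp <- model_loss_grads(m2, sents, train = TRUE)$loss
        m2$par[[nm]][i] <- par[i] - h
        lm <- model_loss_grads(m2, sents, train = TRUE)$loss
        num <- (lp - lm) / (2 * h)
        expect_equal(lg$grads[[nm]][i], num, tolerance = 1e-4,
                     label = paste("grad", nm, i))
      }
    }
  }
})

test_that("the model char-CNN agrees with the standalone char_cnn op", {
  model <- tiny_model(cnn_activation = "tanh")
  sents <- tiny_sentences()
  batch <- cwaner:::prepare_batch(model, sents)
  fw <- cwaner:::model_forward(model, batch, train = FALSE, cache = FALSE)
  # rebuild a filter_bank view of the model's convolution parameters
  bank <- filter_bank(widths = model$config$filter_widths,
                      out_channels = model$config$cnn_output,
                      d_char = model$config$d_char, activation = "tanh")
  for (i in seq_along(bank$filters)) {
    s <- bank$widths[i]
    bank$filters[[i]]$W <- model$par[[paste0("conv_W_", s)]]
    bank$filters[[i]]$b <- model$par[[paste0("conv_b_", s)]]
  }
  tok <- 0L
  for (s in sents) for (j in seq_along(s$words)) {
    tok <- tok + 1L
    rows <- batch$char_rows[tok, ]
    mat <- model$par$E_c[rows, , drop = FALSE]
    expect_equal(unname(fw$c_i[tok, ]),
                 unname(char_cnn(mat, bank, n_real = batch$n_real[tok])),
                 tolerance = 1e-12)
  }
})

test_that("model checkpoints restore an equivalent tagger", {
  model <- tiny_model()
  f <- withr::local_tempfile()
  save_model(model, f)
  back <- load_model(f)
  expect_equal(back$par, model$par)
  s <- tiny_sentences()
  expect_equal(predict_sentences(back, s), predict_sentences(model, s))
  saveRDS(list(format = "other"), f)
  expect_error(load_model(f), "not a cwaner checkpoint")
})
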