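test_that("lexicons are deterministic, ambiguity-controlled and typed", {
  cfg <- small_generator()
  lex <- build_lexicons(cfg)
  expect_identical(lex, build_lexicons(cfg))
  expect_length(lex$entity, 9L)
  expect_true(all(lengths(lex$entity) == cfg$words_per_type))
  # ambiguous words live in both an entity lexicon and the filler pool
  for (ty in names(lex$ambiguous))
    expect_true(all(lex$ambiguous[[ty]] %in% lex$filler))
  # zero ambiguity: entity and filler lexicons are disjoint
  lex0 <- build_lexicons(small_generator(ambiguity_rate = 0))
  expect_length(intersect(unlist(lex0$entity), lex0$filler), 0L)
  # full ambiguity: every entity word also occurs as filler
  lex1 <- build_lexicons(small_generator(ambiguity_rate = 1))
  expect_true(all(unlist(lex1$entity) %in% lex1$filler))
  expect_error(
    build_lexicons(generator_config(char_alphabet_size = 100L,
                                    words_per_type = 20L)),
    "alphabet too small")
})

test_that("generated corpora are deterministic and BIO-consistent", {
  cfg <- small_generator()
  c1 <- generate_corpus(cfg)
  c2 <- generate_corpus(cfg)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_bio(c1$train, f1); write_bio(c2$train, f2)
  expect_identical(readLines(f1, encoding = "UTF-8"),
                   readLines(f2, encoding = "UTF-8"))
  # every sentence round-trips through span decoding and re-encoding
  sc <- label_scheme(cfg$entity_types)
  for (s in c(c1$train[1:40], c1$dev, c1$test)) {
    spans <- bio_decode(s$labels, sc)
    expect_equal(bio_encode(length(s$words), spans, sc), s$labels)
  }
  # empty request
  c0 <- generate_corpus(small_generator(sentences = 0))
  expect_length(c0$train, 0L)
  expect_length(c0$test, 0L)
})

test_that("realized type proportions track the skewed targets", {
  corpus <- generate_corpus(small_generator(sentences = 1500))
  counts <- corpus$manifest$counts
  tot <- rowSums(counts[, c("train", "dev", "test")])
  shares <- tot / sum(tot)
  targets <- corpus$manifest$target_proportions
  expected <- targets * sum(tot)
  for (i in seq_along(targets))
    if (expected[i] >= 50)
      expect_lt(abs(shares[i] - targets[i]) / targets[i], 0.2)
  # the dominant type is the 44%-share one
  expect_equal(which.max(tot), 1L)
  # split sizes follow 70/15/15
  n <- sum(corpus$manifest$sentences)
  expect_equal(unname(corpus$manifest$sentences["train"]) / n, 0.7,
               tolerance = 0.03)
})

test_that("entity characters are informative about the entity type", {
  corpus <- generate_corpus(small_generator(sentences = 800))
  sc <- label_scheme()
  lex <- corpus$lexicons
  # frequency-based character -> type classifier from the training split
  votes <- list()
  for (s in corpus$train) {
    spans <- bio_decode(s$labels, sc)
    for (i in seq_len(nrow(spans))) {
      chs <- unlist(strsplit(s$words[(spans$start[i] + 1):spans$end[i]],
                             ""))
      for (ch in chs) {
        if (is.null(votes[[ch]])) votes[[ch]] <- integer(9)
        k <- match(spans$etype[i], sc$types)
        votes[[ch]][k] <- votes[[ch]][k] + 1L
      }
    }
  }
  char_pred <- vapply(votes, which.max, integer(1))
  # classify test-split entity mentions by majority character vote
  correct <- 0L; total <- 0L
  for (s in corpus$test) {
    spans <- bio_decode(s$labels, sc)
    for (i in seq_len(nrow(spans))) {
      chs <- unlist(strsplit(s$words[(spans$start[i] + 1):spans$end[i]],
                             ""))
      pred <- char_pred[chs]
      pred <- pred[!is.na(pred)]
      if (!length(pred)) next
      tab <- tabulate(pred, 9)
      total <- total + 1L
      if (which.max(tab) == match(spans$etype[i], sc$types))
        correct <- correct + 1L
    }
  }
  # chance level is the majority-class share (~44%)
  expect_gt(correct / total, 0.7)
})

test_that("ambiguous words need context and always carry their cue", {
  cfg <- small_generator(sentences = 1000, ambiguity_rate = 0.3)
  corpus <- generate_corpus(cfg)
  lex <- corpus$lexicons
  amb <- unlist(lex$ambiguous)
  all_sents <- c(corpus$train, corpus$dev, corpus$test)
  seen_entity <- character(); seen_filler <- character()
  for (s in all_sents) {
    is_amb <- s$words %in% amb
    seen_entity <- union(seen_entity, s$words[is_amb & s$labels != "O"])
    seen_filler <- union(seen_filler, s$words[is_amb & s$labels == "O"])
  }
  # some ambiguous words occur under both labels, so no context-free
  # word -> label classifier can be perfect
  expect_gt(length(intersect(seen_entity, seen_filler)), 0L)
  # every ambiguous entity mention has its type cue within two tokens
  # before the span; ambiguous filler occurrences never have one
  for (s in all_sents) {
    spans <- bio_decode(s$labels, label_scheme(cfg$entity_types))
    for (i in seq_len(nrow(spans))) {
      w1 <- s$words[spans$start[i] + 1]
      if (w1 %in% lex$ambiguous[[spans$etype[i]]]) {
        lo <- max(1, spans$start[i] - 1)
        window <- s$words[lo:spans$start[i]]
        expect_true(unname(lex$cues[spans$etype[i]]) %in% window)
      }
    }
    cue_pos <- which(s$words %in% lex$cues)
    amb_filler <- which(s$words %in% amb & s$labels == "O")
    for (pos in amb_filler)
      expect_false(any(abs(cue_pos - pos) <= 2 & cue_pos < pos))
  }
})
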