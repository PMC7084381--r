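# Shared fixtures, built in code.

# The six-token worked example: "patient waist pain increasing 3 years"
# with a body-part, a two-word medical-discovery and a two-word temporal
# entity.
table3_sentence <- function() {
  ner_sentence(
    words = c("患者", "腰部", "疼痛", "加重", "3", "年"),
    labels = c("O", "B-身体部位", "B-医学发现",
               "I-医学发现", "B-时间词", "I-时间词"))
}

table3_spans <- function() {
  entity_spans(c("身体部位", "医学发现", "时间词"),
               c(1L, 2L, 4L), c(2L, 4L, 6L))
}

tiny_scheme <- function() label_scheme(c("disease", "drug"))

tiny_sentences <- function() {
  list(
    ner_sentence(c("aa", "bcc", "d"), c("B-disease", "I-disease", "O")),
    ner_sentence(c("e", "ffgg"), c("O", "B-drug")),
    ner_sentence(c("d", "aa"), c("O", "B-disease")))
}

tiny_model <- function(dropout = 0, seed = 3, num_layers = 2, ...) {
  sents <- tiny_sentences()
  cwae_model(build_vocab(sents), tiny_scheme(),
             cwae_config(d_word = 6, d_char = 4, filter_widths = c(2, 3),
                         cnn_output = 6, d_comp = 6, hidden = 4,
                         num_layers = num_layers, dropout = dropout, ...),
             seed = seed)
}

# a small generator configuration for fast structural tests
small_generator <- function(sentences = 120L, seed = 11L, ...) {
  generator_config(char_alphabet_size = 250L, words_per_type = 20L,
                   filler_words = 60L, sentences = sentences,
                   seed = seed, ...)
}

random_spans <- function(m, scheme) {
  # random non-overlapping spans over [0, m)
  k <- sample(0:(m %/% 2), 1)
  if (k == 0) return(entity_spans())
  cuts <- sort(sample(0:m, 2 * k, replace = FALSE))
  starts <- cuts[seq(1, length(cuts) - 1, by = 2)]
  ends <- cuts[seq(2, length(cuts), by = 2)]
  keep <- ends > starts
  entity_spans(sample(scheme$types, sum(keep), replace = TRUE),
               starts[keep], ends[keep])
}
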