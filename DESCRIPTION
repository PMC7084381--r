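Package: cwaner
Title: Character and Word Attention-Enhanced Neural Named Entity
    Recognition for Chinese Clinical Text
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Sequence-labeling toolkit for medical named entity
    recognition in segmented Chinese clinical text.  Implements
    character-enhanced word embeddings (CWE), a per-word character
    convolutional network, a learned attention gate that mixes
    character-derived and word embeddings, a two-layer bidirectional
    LSTM encoder, and a linear-chain conditional random field with
    exact forward-algorithm and Viterbi inference.  Includes BIO corpus
    readers and writers, strict entity-level evaluation, an
    inter-annotator consistency check, and a synthetic annotated-corpus
    generator for controlled experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
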