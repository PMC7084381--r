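# BIO corpus reading/writing, character padding, vocabulary building.

#' Reserved tokens
#'
#' `pad_token()` is the padding symbol used to extend character sequences
#' to a common length; `unk_token()` stands for out-of-vocabulary words or
#' characters.  Both are reserved: they may not occur as surface forms in
#' a corpus.
#'
#' @return A single string.
#' @export
pad_token <- function() "<PAD>"

#' @rdname pad_token
#' @export
unk_token <- function() "<UNK>"

#' Construct a segmented, BIO-labelled sentence
#'
#' A sentence is an ordered sequence of tokens; each token carries a
#' surface word, its character sequence and a BIO label.  Characters are
#' derived by splitting the surface word and may be PAD-extended with
#' [pad_chars()].
#'
#' @param words Character vector of surface words (length `M >= 1`).
#' @param labels Character vector of BIO labels, same length; defaults to
#'   all-outside.
#' @param chars Optional list of character vectors, one per word; derived
#'   from `words` when `NULL`.
#' @return An object of class `ner_sentence` with elements `words`,
#'   `chars`, `labels`.
#' @export
ner_sentence <- function(words, labels = rep("O", length(words)),
                         chars = NULL) {
  words <- as.character(words)
  labels <- as.character(labels)
  if (length(words) < 1L) stop("a sentence needs at least one token")
  if (length(labels) != length(words))
    stop("labels and words differ in length")
  if (any(words %in% c(pad_token(), unk_token())))
    stop("reserved token used as a surface word")
  if (is.null(chars)) chars <- strsplit(words, "", fixed = TRUE)
  structure(list(words = words, chars = chars, labels = labels),
            class = "ner_sentence")
}

#' @export
print.ner_sentence <- function(x, ...) {
  cat("<ner_sentence> ", length(x$words), " tokens\n", sep = "")
  print(data.frame(word = x$words, label = x$labels))
  invisible(x)
}

#' Read a BIO-annotated corpus
#'
#' Parses a CoNLL-style two-column file: one `token<TAB>label` line per
#' token, UTF-8, sentences separated by blank lines.
#'
#' @param path Path to the file.
#' @param scheme Optional [label_scheme()]; labels are validated against
#'   it.  When `NULL`, labels are only checked against the
#'   `B-`/`I-`/`O` pattern.
#' @return List of [ner_sentence()] objects (possibly empty).
#' @export
read_bio <- function(path, scheme = NULL) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  sentences <- list()
  words <- character(); labels <- character()
  flush <- function() {
    if (length(words)) {
      sentences[[length(sentences) + 1L]] <<- ner_sentence(words, labels)
      words <<- character(); labels <<- character()
    }
  }
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(trimws(ln))) { flush(); next }
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(parts) != 2L)
      stop("line ", i, ": expected 2 tab-separated columns, got ",
           length(parts))
    lab <- parts[2L]
    if (!grepl("^(O|[BI]-.+)$", lab))
      stop("line ", i, ": label '", lab, "' not of form O, B-<type>, I-<type>")
    if (!is.null(scheme) && !lab %in% scheme$labels)
      stop("line ", i, ": label '", lab, "' outside scheme alphabet")
    words[[length(words) + 1L]] <- parts[1L]
    labels[[length(labels) + 1L]] <- lab
  }
  flush()
  sentences
}

#' Write a BIO-annotated corpus
#'
#' Inverse of [read_bio()]: `read_bio(write_bio(s, f))` reproduces `s`.
#'
#' @param sentences List of [ner_sentence()] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bio <- function(sentences, path) {
  blocks <- vapply(sentences, function(s) {
    if (any(s$words %in% c(pad_token(), unk_token())))
      stop("reserved token used as a surface word")
    paste(paste(s$words, s$labels, sep = "\t"), collapse = "\n")
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(blocks))
    writeLines(enc2utf8(paste(blocks, collapse = "\n\n")), con,
               useBytes = TRUE)
  invisible(path)
}

#' Pad character sequences to a common length
#'
#' Right-pads every token's character sequence with [pad_token()] so that
#' all have length `w_l`; by default `w_l` is the longest word in the
#' sentence.  During training the same rule is applied per mini-batch, so
#' `w_l` is the longest word in the batch.  Idempotent.
#'
#' @param sentence A [ner_sentence()].
#' @param w_l Target character length; defaults to the sentence maximum.
#' @return The sentence with uniform character lengths.
#' @export
pad_chars <- function(sentence, w_l = NULL) {
  lens <- lengths(sentence$chars)
  if (is.null(w_l)) w_l <- max(lens)
  if (any(lens > w_l)) stop("w_l smaller than an existing character sequence")
  sentence$chars <- lapply(sentence$chars, function(cs)
    c(cs, rep(pad_token(), w_l - length(cs))))
  sentence
}

#' Build word and character vocabularies
#'
#' Assigns dense integer ids to words and characters.  Id 0 is reserved
#' for [pad_token()] and id 1 for [unk_token()] in both maps; remaining
#' ids follow first-occurrence order, so identical input yields identical
#' vocabularies.  Tokens rarer than `min_count` are dropped (they map to
#' the unknown id at lookup time).
#'
#' @param sentences Non-empty list of [ner_sentence()] objects.
#' @param min_count Minimum frequency for a token to receive its own id.
#' @return An object of class `ner_vocab` with named integer vectors
#'   `word_index` and `char_index` (0-based ids) and the matching
#'   frequency vectors `word_count`, `char_count`.
#' @export
build_vocab <- function(sentences, min_count = 1L) {
  stopifnot(min_count >= 1L)
  if (length(sentences) == 0L) stop("empty corpus")
  words <- unlist(lapply(sentences, `[[`, "words"), use.names = FALSE)
  chars <- unlist(lapply(sentences, function(s)
    unlist(s$chars, use.names = FALSE)), use.names = FALSE)
  chars <- chars[chars != pad_token()]
  index_of <- function(tokens) {
    counts <- table(factor(tokens, levels = unique(tokens)))
    keep <- counts[counts >= min_count]
    ids <- c(0L, 1L, seq_along(keep) + 1L)
    names(ids) <- c(pad_token(), unk_token(), names(keep))
    cnt <- c(0L, 0L, as.integer(keep))
    names(cnt) <- names(ids)
    list(index = ids, count = cnt)
  }
  w <- index_of(words); ch <- index_of(chars)
  structure(list(word_index = w$index, word_count = w$count,
                 char_index = ch$index, char_count = ch$count),
            class = "ner_vocab")
}

#' @export
print.ner_vocab <- function(x, ...) {
  cat("<ner_vocab> ", length(x$word_index) - 2L, " words, ",
      length(x$char_index) - 2L, " characters (+PAD, +UNK)\n", sep = "")
  invisible(x)
}

#' Look up token ids with unknown fallback
#'
#' @param tokens Character vector.
#' @param index A 0-based id map from [build_vocab()].
#' @return Integer vector of 0-based ids; unseen tokens get the unknown id.
#' @export
vocab_lookup <- function(tokens, index) {
  ids <- index[tokens]
  ids[is.na(ids)] <- index[[unk_token()]]
  unname(ids)
}

#' Serialize / restore a vocabulary
#'
#' One `token<TAB>id<TAB>count` line per entry, UTF-8.
#'
#' @param vocab A `ner_vocab`.
#' @param path Output file.
#' @return `path` (write) or a `ner_vocab` (read).
#' @export
write_vocab <- function(vocab, path) {
  fmt <- function(index, count)
    paste(names(index), unname(index), unname(count), sep = "\t")
  lines <- c("#words", fmt(vocab$word_index, vocab$word_count),
             "#chars", fmt(vocab$char_index, vocab$char_count))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(enc2utf8(lines), con, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_vocab
#' @export
read_vocab <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  cut <- which(lines == "#chars")
  parse <- function(ls) {
    parts <- strsplit(ls, "\t", fixed = TRUE)
    idx <- vapply(parts, function(p) as.integer(p[2L]), integer(1))
    cnt <- vapply(parts, function(p) as.integer(p[3L]), integer(1))
    names(idx) <- names(cnt) <- vapply(parts, `[[`, character(1), 1L)
    list(index = idx, count = cnt)
  }
  w <- parse(lines[2:(cut - 1L)])
  ch <- parse(lines[(cut + 1L):length(lines)])
  structure(list(word_index = w$index, word_count = w$count,
                 char_index = ch$index, char_count = ch$count),
            class = "ner_vocab")
}
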