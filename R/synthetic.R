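# Synthetic annotated-corpus generator.
#
# Emulates the statistical structure of annotated clinical admission
# notes: nine entity types with strongly skewed frequencies, words of
# 1-4 characters, entity words whose characters are type-indicative,
# ambiguous words that are entities only in the right context, and
# generic filler vocabulary.  "Characters" are abstract symbols rendered
# as Unicode private-use code points, so the whole pipeline exercises
# real multi-byte text handling.

#' Synthetic-corpus generator configuration
#'
#' @param entity_types Entity-type names (default the nine clinical
#'   types).
#' @param type_proportions Target share of entity mentions per type;
#'   defaults to the skewed clinical distribution (about 44% medical
#'   discovery down to 2% medication).  Must sum to 1 (within 1e-6
#'   before normalization).
#' @param char_alphabet_size Number of distinct symbols.
#' @param words_per_type Entity lexicon size per type.
#' @param filler_words Filler lexicon size.
#' @param word_length_range Min/max characters per word.
#' @param sentences Total sentences to generate (split 70/15/15).
#' @param mean_sentence_length Mean tokens per sentence (truncated
#'   geometric length distribution).
#' @param entity_density Expected entity mentions per token.
#' @param multiword_rate Fraction of entity mentions spanning two words.
#' @param ambiguity_rate Fraction of each entity lexicon that also
#'   occurs as filler; such words are entities only when a type-specific
#'   cue word appears within two tokens before the mention.
#' @param char_purity Probability that a character of an entity word is
#'   drawn from the type's characteristic character set (the remainder
#'   comes from the shared pool).
#' @param zipf_exponent Word-frequency skew within each lexicon.
#' @param seed RNG seed; generation is fully deterministic given it.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(
    entity_types = clinical_entity_types(),
    type_proportions = c(0.4396, 0.0244, 0.1033, 0.0318, 0.0388,
                         0.0424, 0.0790, 0.0201, 0.2234),
    char_alphabet_size = 400L, words_per_type = 300L,
    filler_words = 500L, word_length_range = c(1L, 4L),
    sentences = 2857L, mean_sentence_length = 12,
    entity_density = 0.22, multiword_rate = 0.3,
    ambiguity_rate = 0.1, char_purity = 0.8, zipf_exponent = 1,
    seed = 1L) {
  if (length(type_proportions) != length(entity_types))
    stop("one proportion per entity type required")
  if (abs(sum(type_proportions) - 1) > 1e-2)
    stop("type proportions must sum to ~1")
  type_proportions <- type_proportions / sum(type_proportions)
  stopifnot(char_alphabet_size >= 50L, words_per_type >= 1L,
            filler_words >= 1L, sentences >= 0L,
            mean_sentence_length >= 3, entity_density > 0,
            entity_density < 0.5, ambiguity_rate >= 0, ambiguity_rate <= 1,
            char_purity >= 0, char_purity <= 1)
  structure(list(entity_types = entity_types,
                 type_proportions = type_proportions,
                 char_alphabet_size = as.integer(char_alphabet_size),
                 words_per_type = as.integer(words_per_type),
                 filler_words = as.integer(filler_words),
                 word_length_range = as.integer(word_length_range),
                 sentences = as.integer(sentences),
                 mean_sentence_length = mean_sentence_length,
                 entity_density = entity_density,
                 multiword_rate = multiword_rate,
                 ambiguity_rate = ambiguity_rate,
                 char_purity = char_purity,
                 zipf_exponent = zipf_exponent,
                 seed = as.integer(seed)),
            class = "generator_config")
}

pua_symbols <- function(n) vapply(seq_len(n) - 1L,
                                  function(i) intToUtf8(0xE000 + i),
                                  character(1))

zipf_weights <- function(n, s) (seq_len(n))^(-s)

#' Build entity, filler and cue lexicons
#'
#' Each entity type owns a disjoint set of characteristic symbols;
#' entity words draw most characters from it (see `char_purity`), so
#' character identity carries type information.  A fraction
#' `ambiguity_rate` of each entity lexicon is also added to the filler
#' lexicon.  Each type gets one reserved cue word that only ever
#' accompanies ambiguous entity mentions.
#'
#' @param cfg A [generator_config()].
#' @return List with `entity` (per-type word vectors), `filler`,
#'   `ambiguous` (per-type vectors), `cues` (named vector), and
#'   `type_chars` (per-type symbol vectors).
#' @export
build_lexicons <- function(cfg) {
  n_ty <- length(cfg$entity_types)
  chars_per_type <- 20L
  n_typed <- n_ty * chars_per_type
  if (cfg$char_alphabet_size < n_typed + 30L)
    stop("alphabet too small: need at least ", n_typed + 30L, " symbols")
  alphabet <- pua_symbols(cfg$char_alphabet_size)
  type_chars <- split(alphabet[seq_len(n_typed)],
                      rep(seq_len(n_ty), each = chars_per_type))
  names(type_chars) <- cfg$entity_types
  shared <- alphabet[(n_typed + 1L):cfg$char_alphabet_size]
  lo <- cfg$word_length_range[1L]; hi <- cfg$word_length_range[2L]
  len_w <- c(0.15, 0.45, 0.25, 0.15)[seq_len(hi - lo + 1L)]

  with_seed(cfg$seed, {
    seen <- new.env(hash = TRUE)
    make_word <- function(typed, purity) {
      for (try in 1:200) {
        l <- sample(lo:hi, 1L, prob = len_w)
        cs <- vapply(seq_len(l), function(j) {
          if (length(typed) && stats::runif(1) < purity) sample(typed, 1L)
          else sample(shared, 1L)
        }, character(1))
        w <- paste(cs, collapse = "")
        if (is.null(seen[[w]])) { seen[[w]] <- TRUE; return(w) }
      }
      stop("alphabet too small for the requested lexicon sizes")
    }
    entity <- lapply(cfg$entity_types, function(ty)
      vapply(seq_len(cfg$words_per_type), function(i)
        make_word(type_chars[[ty]], cfg$char_purity), character(1)))
    names(entity) <- cfg$entity_types
    filler <- vapply(seq_len(cfg$filler_words), function(i)
      make_word(character(), 0), character(1))
    cues <- vapply(cfg$entity_types, function(ty)
      make_word(character(), 0), character(1))
    n_amb <- ceiling(cfg$ambiguity_rate * cfg$words_per_type)
    ambiguous <- lapply(entity, function(ws)
      if (n_amb > 0L) sample(ws, min(n_amb, length(ws))) else character())
    if (n_amb > 0L)
      filler <- c(filler, unlist(ambiguous, use.names = FALSE))
    list(entity = entity, filler = filler, ambiguous = ambiguous,
         cues = cues, type_chars = type_chars)
  })
}

#' Generate a synthetic annotated corpus
#'
#' Sentences interleave filler runs with entity mentions.  Entity-type
#' counts follow the target proportions by largest-remainder quota, so
#' realized shares are exact up to rounding; mention order, word choice
#' (Zipf-weighted within each lexicon), sentence lengths and the
#' 70/15/15 stratified split are all driven by the seed.  Ambiguous
#' entity mentions always carry their type's cue word one or two tokens
#' before the mention; ambiguous filler occurrences never do.
#'
#' @param cfg A [generator_config()].
#' @return An object of class `synthetic_corpus`: list with `train`,
#'   `dev`, `test` (lists of [ner_sentence()]s), `lexicons`, and
#'   `manifest` (gold span counts per type and split).
#' @export
generate_corpus <- function(cfg = generator_config()) {
  lex <- build_lexicons(cfg)
  scheme <- label_scheme(cfg$entity_types)
  n_ty <- length(cfg$entity_types)
  empty <- structure(list(train = list(), dev = list(), test = list(),
                          lexicons = lex,
                          manifest = list(scheme = scheme$types,
                                          counts = NULL)),
                     class = "synthetic_corpus")
  if (cfg$sentences == 0L) return(empty)

  with_seed((cfg$seed %% 1000000L) + 1L, {   # stay well inside integer range
    n <- cfg$sentences
    p_geom <- 1 / (cfg$mean_sentence_length - 2)
    lens <- pmin(3L + stats::rgeom(n, p_geom), 40L)
    slots <- stats::rbinom(n, pmax(1L, lens %/% 3L),
                           min(1, 3 * cfg$entity_density))
    total <- sum(slots)
    # largest-remainder quota over entity types
    quota <- cfg$type_proportions * total
    cnt <- floor(quota)
    rem <- order(quota - cnt, decreasing = TRUE)
    short <- total - sum(cnt)
    if (short > 0L) cnt[rem[seq_len(short)]] <- cnt[rem[seq_len(short)]] + 1L
    type_seq <- sample(rep(seq_len(n_ty), cnt))

    zf <- lapply(lex$entity, function(ws)
      zipf_weights(length(ws), cfg$zipf_exponent))
    zfill <- zipf_weights(length(lex$filler), cfg$zipf_exponent)
    amb_all <- lapply(lex$ambiguous, function(a) a)
    amb_flat <- unlist(lex$ambiguous, use.names = FALSE)
    # unambiguous filler, used next to cue words so that a cue within
    # two tokens before an ambiguous word always signals an entity
    filler_clean <- setdiff(lex$filler, amb_flat)

    groups <- sample.int(6L, n, replace = TRUE,
                         prob = c(0.11, 0.05, 0.10, 0.33, 0.14, 0.27))
    sentences <- vector("list", n)
    used <- 0L
    for (si in seq_len(n)) {
      k <- slots[si]
      ty_ids <- if (k > 0L) type_seq[used + seq_len(k)] else integer()
      used <- used + k
      mentions <- lapply(ty_ids, function(ti) {
        ws <- lex$entity[[ti]]
        nwords <- if (stats::runif(1) < cfg$multiword_rate) 2L else 1L
        idx <- sample.int(length(ws), nwords, replace = TRUE, prob = zf[[ti]])
        words <- ws[idx]
        list(type = cfg$entity_types[ti], words = words,
             ambiguous = any(words %in% amb_all[[ti]]))
      })
      ent_tokens <- sum(vapply(mentions, function(m) length(m$words),
                               integer(1)))
      n_fill <- max(lens[si] - ent_tokens, length(mentions) + 1L)
      fill <- lex$filler[sample.int(length(lex$filler), n_fill,
                                    replace = TRUE, prob = zfill)]
      # distribute filler into k+1 runs (each at least 1 to keep cue
      # placement unambiguous)
      runs <- length(mentions) + 1L
      alloc <- rep(1L, runs)
      extra <- n_fill - runs
      if (extra > 0L) {
        add <- table(sample.int(runs, extra, replace = TRUE))
        alloc[as.integer(names(add))] <- alloc[as.integer(names(add))] +
          as.integer(add)
      }
      words <- character(); spans_ty <- character()
      spans_s <- integer(); spans_e <- integer()
      fpos <- 0L
      for (r in seq_len(runs)) {
        run <- fill[fpos + seq_len(alloc[r])]
        fpos <- fpos + alloc[r]
        if (r <= length(mentions) && mentions[[r]]$ambiguous) {
          # cue lands one or two tokens before the mention
          cue_off <- if (length(run) >= 2L) sample.int(2L, 1L) - 1L else 0L
          run <- append(run, unname(lex$cues[mentions[[r]]$type]),
                        after = length(run) - cue_off)
        }
        words <- c(words, run)
        if (r <= length(mentions)) {
          m <- mentions[[r]]
          spans_ty <- c(spans_ty, m$type)
          spans_s <- c(spans_s, length(words))
          spans_e <- c(spans_e, length(words) + length(m$words))
          words <- c(words, m$words)
        }
      }
      # a cue may only ever sit within two tokens before an ambiguous
      # word when that word is the entity it cues, so scrub ambiguous
      # filler out of the two positions after each cue
      covered <- logical(length(words))
      for (j in seq_along(spans_ty))
        covered[(spans_s[j] + 1L):spans_e[j]] <- TRUE
      for (pos in which(words %in% lex$cues)) {
        for (d in 1:2) {
          q <- pos + d
          if (q <= length(words) && !covered[q] && words[q] %in% amb_flat)
            words[q] <- filler_clean[sample.int(length(filler_clean), 1L)]
        }
      }
      spans <- entity_spans(spans_ty, spans_s, spans_e)
      sent <- ner_sentence(words, bio_encode(length(words), spans, scheme))
      attr(sent, "group") <- groups[si]
      sentences[[si]] <- sent
    }

    # stratified 70/15/15 split by synthetic group label
    train <- dev <- test <- list()
    for (gr in sort(unique(groups))) {
      members <- which(groups == gr)
      members <- members[sample.int(length(members))]
      n_g <- length(members)
      n_tr <- round(0.7 * n_g); n_dv <- round(0.15 * n_g)
      train <- c(train, sentences[members[seq_len(n_tr)]])
      dev <- c(dev, sentences[members[n_tr + seq_len(n_dv)]])
      test <- c(test, sentences[members[setdiff(seq_len(n_g),
                                                seq_len(n_tr + n_dv))]])
    }

    count_types <- function(ss) {
      spans <- lapply(ss, function(s) bio_decode(s$labels, scheme))
      tab <- table(factor(unlist(lapply(spans, `[[`, "etype")),
                          levels = scheme$types))
      as.integer(tab)
    }
    manifest <- list(
      scheme = scheme$types,
      counts = data.frame(etype = scheme$types,
                          train = count_types(train),
                          dev = count_types(dev),
                          test = count_types(test)),
      target_proportions = cfg$type_proportions,
      sentences = c(train = length(train), dev = length(dev),
                    test = length(test)))
    structure(list(train = train, dev = dev, test = test,
                   lexicons = lex, manifest = manifest),
              class = "synthetic_corpus")
  })
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  cat("<synthetic_corpus> train/dev/test = ",
      length(x$train), "/", length(x$dev), "/", length(x$test),
      " sentences\n", sep = "")
  invisible(x)
}
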