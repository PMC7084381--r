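# Label scheme and BIO span arithmetic.

#' Default clinical entity-type inventory
#'
#' The nine medical entity types used throughout the package: medical
#' discovery, temporal word, inspection, laboratory test, treatment,
#' measurement, disease, medication and body part (in that order).
#'
#' @return Character vector of nine entity-type names.
#' @export
clinical_entity_types <- function() {
  c("医学发现",  # medical discovery
    "时间词",        # temporal word
    "检查",              # inspection
    "检验",              # laboratory test
    "治疗",              # treatment
    "测量数据",  # measurement
    "疾病",              # disease
    "药物",              # medication
    "身体部位")  # body part
}

#' Build a BIO label scheme from entity types
#'
#' Derives the BIO label alphabet from an ordered inventory of entity
#' types: one outside label `"O"` plus a `B-`/`I-` pair per type, giving
#' `2 * length(types) + 1` labels.  With the default nine clinical types
#' this yields the 19-label alphabet used by the tagger.
#'
#' @param types Character vector of entity-type names (unique, non-empty).
#' @return An object of class `label_scheme` with elements `types`,
#'   `labels` (the alphabet, `"O"` first) and `T` (label count).
#' @examples
#' sc <- label_scheme(c("disease", "drug"))
#' sc$T  # 5
#' @export
label_scheme <- function(types = clinical_entity_types()) {
  types <- as.character(types)
  if (length(types) < 1L || anyDuplicated(types) || any(!nzchar(types)))
    stop("entity types must be a non-empty vector of unique, non-empty names")
  labels <- c("O", as.vector(rbind(paste0("B-", types), paste0("I-", types))))
  structure(list(types = types, labels = labels, T = length(labels)),
            class = "label_scheme")
}

#' @export
print.label_scheme <- function(x, ...) {
  cat("<label_scheme> ", length(x$types), " entity types, ",
      x$T, " BIO labels\n", sep = "")
  invisible(x)
}

#' Construct an entity-span table
#'
#' Spans are 0-based, half-open `[start, end)` over token positions.
#'
#' @param etype Character vector of entity-type names.
#' @param start,end Integer vectors; `0 <= start < end`.
#' @return A `data.frame` with columns `etype`, `start`, `end`.
#' @export
entity_spans <- function(etype = character(), start = integer(),
                         end = integer()) {
  df <- data.frame(etype = as.character(etype),
                   start = as.integer(start), end = as.integer(end),
                   stringsAsFactors = FALSE)
  if (nrow(df) && any(df$start < 0L | df$end <= df$start))
    stop("spans must satisfy 0 <= start < end")
  df
}

validate_spans <- function(spans, m = NULL, scheme = NULL) {
  stopifnot(is.data.frame(spans),
            all(c("etype", "start", "end") %in% names(spans)))
  if (nrow(spans) == 0L) return(invisible(spans))
  if (any(spans$start < 0L | spans$end <= spans$start))
    stop("invalid span bounds: need 0 <= start < end")
  if (!is.null(m) && any(spans$end > m))
    stop("span exceeds sentence length ", m)
  if (!is.null(scheme) && !all(spans$etype %in% scheme$types))
    stop("unknown entity type: ",
         paste(setdiff(spans$etype, scheme$types), collapse = ", "))
  o <- order(spans$start)
  s <- spans[o, , drop = FALSE]
  if (nrow(s) > 1L && any(s$start[-1L] < s$end[-nrow(s)]))
    stop("overlapping spans")
  invisible(spans)
}

#' Encode entity spans as a BIO label sequence
#'
#' The first token of a span gets `B-<type>`, later tokens `I-<type>`,
#' and all remaining positions the outside label `"O"`.
#'
#' @param m Sentence length in tokens.
#' @param spans Span table as from [entity_spans()]; non-overlapping,
#'   within `[0, m)`.
#' @param scheme A [label_scheme()].
#' @return Character vector of `m` BIO labels.
#' @export
bio_encode <- function(m, spans, scheme) {
  m <- as.integer(m)
  stopifnot(m >= 0L)
  validate_spans(spans, m = m, scheme = scheme)
  labels <- rep("O", m)
  for (i in seq_len(nrow(spans))) {
    s <- spans$start[i]; e <- spans$end[i]
    labels[s + 1L] <- paste0("B-", spans$etype[i])
    if (e - s > 1L)
      labels[(s + 2L):e] <- paste0("I-", spans$etype[i])
  }
  labels
}

#' Decode a BIO label sequence into entity spans
#'
#' Inverse of [bio_encode()] on valid sequences.  Invalid sequences are
#' repaired with the conventional "I-as-B" rule: an `I-x` that is not
#' preceded by `B-x` or `I-x` opens a new `x` span.  This matters because
#' an unconstrained CRF decoder can emit label sequences that violate the
#' BIO grammar.
#'
#' @param labels Character vector of BIO labels from the scheme alphabet.
#' @param scheme A [label_scheme()].
#' @return Span table sorted by `start`; spans never overlap.
#' @export
bio_decode <- function(labels, scheme) {
  if (!all(labels %in% scheme$labels))
    stop("label outside scheme alphabet: ",
         paste(setdiff(labels, scheme$labels), collapse = ", "))
  n <- length(labels)
  etype <- character(); start <- integer(); end <- integer()
  cur_type <- NA_character_; cur_start <- NA_integer_
  close_span <- function(pos) {
    if (!is.na(cur_type)) {
      etype[[length(etype) + 1L]] <<- cur_type
      start[[length(start) + 1L]] <<- cur_start
      end[[length(end) + 1L]] <<- pos
      cur_type <<- NA_character_
    }
  }
  for (i in seq_len(n)) {
    lab <- labels[i]
    if (lab == "O") {
      close_span(i - 1L)
    } else {
      tag <- substr(lab, 1L, 1L)
      typ <- substr(lab, 3L, nchar(lab))
      if (tag == "B" || is.na(cur_type) || cur_type != typ) {
        # B- always opens; orphan or type-switching I- repaired to B-
        close_span(i - 1L)
        cur_type <- typ
        cur_start <- i - 1L
      }
    }
  }
  close_span(n)
  entity_spans(etype, start, end)
}
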