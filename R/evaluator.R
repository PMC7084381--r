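# Strict entity-level evaluation and inter-annotator consistency.

#' Match predicted against gold entity spans
#'
#' Strict matching: a predicted span is a true positive iff an unmatched
#' gold span has the identical (type, start, end) triple; a boundary or
#' type error is a full miss (one FP plus one FN).  Counts are
#' accumulated per entity type and pooled overall.
#'
#' @param gold,pred Span tables ([entity_spans()]) for one sentence, or
#'   lists of span tables for parallel sentences.
#' @return An object of class `match_counts`: `per_type` data.frame with
#'   columns `etype`, `tp`, `fp`, `fn`, and `overall` (named vector of
#'   pooled counts).
#' @export
match_spans <- function(gold, pred) {
  if (is.data.frame(gold)) gold <- list(gold)
  if (is.data.frame(pred)) pred <- list(pred)
  if (length(gold) != length(pred))
    stop("gold and pred cover different numbers of sentences")
  tp <- fp <- fn <- structure(numeric(), names = character())
  bump <- function(tab, types) {
    for (ty in types) tab[ty] <- (if (ty %in% names(tab)) tab[ty] else 0) + 1
    tab
  }
  for (i in seq_along(gold)) {
    g <- gold[[i]]; p <- pred[[i]]
    validate_spans(g); validate_spans(p)
    gk <- paste(g$etype, g$start, g$end)
    pk <- paste(p$etype, p$start, p$end)
    hit <- pk %in% gk
    tp <- bump(tp, p$etype[hit])
    fp <- bump(fp, p$etype[!hit])
    fn <- bump(fn, g$etype[!gk %in% pk])
  }
  types <- sort(unique(c(names(tp), names(fp), names(fn))))
  per_type <- data.frame(
    etype = types,
    tp = as.numeric(tp[types]), fp = as.numeric(fp[types]),
    fn = as.numeric(fn[types]), stringsAsFactors = FALSE)
  per_type[is.na(per_type)] <- 0
  structure(list(per_type = per_type,
                 overall = c(tp = sum(per_type$tp), fp = sum(per_type$fp),
                             fn = sum(per_type$fn))),
            class = "match_counts")
}

prf_one <- function(tp, fp, fn) {
  p <- if (tp + fp > 0) 100 * tp / (tp + fp) else 0
  r <- if (tp + fn > 0) 100 * tp / (tp + fn) else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(P = p, R = r, F1 = f1)
}

#' Precision, recall and F1 from match counts
#'
#' `P = TP/(TP+FP)`, `R = TP/(TP+FN)`, `F1 = 2PR/(P+R)`, on the percent
#' scale (94.44 rather than 0.9444).  Zero denominators yield 0 by
#' convention.  The overall row micro-averages by pooling counts across
#' types.
#'
#' @param counts A `match_counts` from [match_spans()].
#' @return An object of class `prf_report`: `per_type` data.frame with
#'   `etype`, `tp`, `fp`, `fn`, `P`, `R`, `F1`, and `overall` (list with
#'   `P`, `R`, `F1`).
#' @export
prf <- function(counts) {
  pt <- counts$per_type
  mets <- t(mapply(prf_one, pt$tp, pt$fp, pt$fn))
  if (nrow(pt) == 0L) mets <- matrix(numeric(), 0L, 3L,
                                     dimnames = list(NULL, c("P", "R", "F1")))
  ov <- prf_one(counts$overall[["tp"]], counts$overall[["fp"]],
                counts$overall[["fn"]])
  structure(list(per_type = cbind(pt, as.data.frame(mets)),
                 overall = as.list(ov)),
            class = "prf_report")
}

#' @export
print.prf_report <- function(x, digits = 2, ...) {
  df <- x$per_type
  if (nrow(df)) {
    df$P <- round(df$P, digits); df$R <- round(df$R, digits)
    df$F1 <- round(df$F1, digits)
    print(df, row.names = FALSE)
  }
  cat(sprintf("overall: P %.2f  R %.2f  F1 %.2f\n",
              x$overall$P, x$overall$R, x$overall$F1))
  invisible(x)
}

#' Evaluate predictions against gold sentences
#'
#' Decodes both label sequences to entity spans and scores them with
#' strict matching.
#'
#' @param gold,pred Parallel lists of [ner_sentence()]s.
#' @param scheme The [label_scheme()].
#' @return A `prf_report`.
#' @export
evaluate_corpus <- function(gold, pred, scheme) {
  if (length(gold) != length(pred))
    stop("gold and pred differ in length")
  gs <- lapply(gold, function(s) bio_decode(s$labels, scheme))
  ps <- lapply(pred, function(s) bio_decode(s$labels, scheme))
  prf(match_spans(gs, ps))
}

#' Inter-annotator consistency
#'
#' For two annotators A and B over the same documents:
#' `P = |A intersect B| / |B|`, `R = |A intersect B| / |A|`,
#' `F = 2PR/(P+R)`, with spans intersected by exact (type, start, end)
#' identity.  Reported as fractions in `[0, 1]`.  `F` is symmetric in A
#' and B, and `P(A,B) = R(B,A)`.
#'
#' @param spans_a,spans_b Span tables or lists of span tables (one per
#'   document) from annotators A and B.
#' @return Named list with `P`, `R`, `F`.
#' @export
annotator_consistency <- function(spans_a, spans_b) {
  if (is.data.frame(spans_a)) spans_a <- list(spans_a)
  if (is.data.frame(spans_b)) spans_b <- list(spans_b)
  if (length(spans_a) != length(spans_b))
    stop("annotators cover different numbers of documents")
  n_a <- 0; n_b <- 0; n_both <- 0
  for (i in seq_along(spans_a)) {
    ka <- paste(spans_a[[i]]$etype, spans_a[[i]]$start, spans_a[[i]]$end)
    kb <- paste(spans_b[[i]]$etype, spans_b[[i]]$start, spans_b[[i]]$end)
    n_a <- n_a + length(ka); n_b <- n_b + length(kb)
    n_both <- n_both + length(intersect(ka, kb))
  }
  p <- if (n_b > 0) n_both / n_b else 0
  r <- if (n_a > 0) n_both / n_a else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  list(P = p, R = r, F = f)
}
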