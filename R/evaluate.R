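# Span-based evaluation: exact-match micro-averaged precision/recall/F1,
# per-type breakdown, and gene-mention style alternative-annotation credit.

new_eval_result <- function(tp, fp, fn) {
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  structure(list(tp = tp, fp = fp, fn = fn,
                 precision = p, recall = r, f1 = f1),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("TP %d  FP %d  FN %d | P %.4f  R %.4f  F1 %.4f\n",
              x$tp, x$fp, x$fn, x$precision, x$recall, x$f1))
  invisible(x)
}

span_key <- function(spans) {
  if (!nrow(spans)) return(character(0))
  paste(spans$start, spans$end, spans$type, sep = "|")
}

check_alignment <- function(gold, predicted) {
  if (length(gold) != length(predicted)) {
    stop_config("corpora misaligned: %d gold vs %d predicted sentences",
                length(gold), length(predicted))
  }
  for (i in seq_along(gold)) {
    if (length(gold[[i]]$tags) != length(predicted[[i]]$tags)) {
      stop_config("corpora misaligned at sentence %d: %d vs %d tokens",
                  i, length(gold[[i]]$tags), length(predicted[[i]]$tags))
    }
  }
}

# One-to-one exact matching of two span sets within a sentence; returns tp.
match_exact <- function(gold_keys, pred_keys) {
  tp <- 0L
  avail <- gold_keys
  for (k in pred_keys) {
    hit <- match(k, avail)
    if (!is.na(hit)) { tp <- tp + 1L; avail <- avail[-hit] }
  }
  tp
}

#' Score a predicted corpus against gold annotations
#'
#' Entities are extracted from both tag sequences with [bieos_to_spans()]
#' (invalid predicted sequences are repaired, never rejected). A predicted
#' span is a true positive iff a not-yet-matched gold span with identical
#' boundaries and type exists in the same sentence; matching is
#' one-to-one. Counts are pooled over the whole corpus (micro-average)
#' before computing `P = TP/(TP+FP)`, `R = TP/(TP+FN)` and
#' `F1 = 2PR/(P+R)`.
#'
#' @param gold list of gold sentences (`tokens`/`tags`).
#' @param predicted list of predicted sentences, aligned with `gold`.
#' @return an `eval_result`: counts `tp`/`fp`/`fn` and derived
#'   `precision`/`recall`/`f1`.
#' @export
score_corpus <- function(gold, predicted) {
  check_alignment(gold, predicted)
  tp <- 0L; n_gold <- 0L; n_pred <- 0L
  for (i in seq_along(gold)) {
    gk <- span_key(bieos_to_spans(gold[[i]]$tags))
    pk <- span_key(bieos_to_spans(predicted[[i]]$tags))
    tp <- tp + match_exact(gk, pk)
    n_gold <- n_gold + length(gk)
    n_pred <- n_pred + length(pk)
  }
  new_eval_result(tp, n_pred - tp, n_gold - tp)
}

#' Score with alternative-annotation credit
#'
#' Gene-mention style scoring: each gold entity carries a primary span and
#' optionally alternative acceptable spans of the same type; a prediction
#' matching \emph{any} span of a not-yet-consumed gold entity of the same
#' type counts as a true positive. Each gold entity credits at most one
#' prediction and each prediction consumes at most one entity; leftover
#' gold entities are false negatives and leftover predictions false
#' positives.
#'
#' @param gold list of gold sentences (their primary annotation, as tags).
#' @param predicted aligned predicted sentences.
#' @param alternatives records from [read_alternatives()] (or an empty
#'   list, which reduces to [score_corpus()] except that gold entities are
#'   taken from the sidecar when listed).
#' @return an `eval_result`.
#' @export
score_with_alternatives <- function(gold, predicted, alternatives = list()) {
  check_alignment(gold, predicted)
  # per-sentence entity records: primary + alternatives
  ents <- vector("list", length(gold))
  for (i in seq_along(gold)) {
    sp <- bieos_to_spans(gold[[i]]$tags)
    ents[[i]] <- lapply(seq_len(nrow(sp)), function(r) {
      list(type = sp$type[r],
           spans = matrix(c(sp$start[r], sp$end[r]), ncol = 2,
                          dimnames = list(NULL, c("start", "end"))))
    })
  }
  for (a in alternatives) {
    i <- a$sentence
    if (i < 1L || i > length(gold)) {
      stop_config("alternatives record references sentence %d of %d", i, length(gold))
    }
    len <- length(gold[[i]]$tags)
    if (any(a$spans[, "end"] > len)) {
      stop_config("alternative span beyond sentence %d length %d", i, len)
    }
    # attach to the gold entity whose primary span equals the record's first
    prim <- a$spans[1L, ]
    hit <- which(vapply(ents[[i]], function(e) {
      e$type == a$type && e$spans[1L, "start"] == prim[["start"]] &&
        e$spans[1L, "end"] == prim[["end"]]
    }, logical(1)))
    if (!length(hit)) {
      stop_config("alternatives record for sentence %d does not match a gold entity", i)
    }
    ents[[i]][[hit[1L]]]$spans <- a$spans
  }
  tp <- 0L; n_gold <- 0L; n_pred <- 0L
  for (i in seq_along(gold)) {
    pred_sp <- bieos_to_spans(predicted[[i]]$tags)
    n_pred <- n_pred + nrow(pred_sp)
    n_gold <- n_gold + length(ents[[i]])
    consumed <- rep(FALSE, length(ents[[i]]))
    for (r in seq_len(nrow(pred_sp))) {
      for (e in seq_along(ents[[i]])) {
        if (consumed[e]) next
        ent <- ents[[i]][[e]]
        if (ent$type == pred_sp$type[r] &&
            any(ent$spans[, "start"] == pred_sp$start[r] &
                ent$spans[, "end"] == pred_sp$end[r])) {
          consumed[e] <- TRUE
          tp <- tp + 1L
          break
        }
      }
    }
  }
  new_eval_result(tp, n_pred - tp, n_gold - tp)
}

#' Per-entity-type evaluation breakdown
#'
#' Partitions the exact-match counts by entity type: a span with the right
#' boundaries but the wrong type contributes a false positive under the
#' predicted type and a false negative under the gold type. The per-type
#' counts sum to the overall [score_corpus()] counts.
#'
#' @inheritParams score_corpus
#' @return named list mapping each entity type to an `eval_result`.
#' @export
per_type_breakdown <- function(gold, predicted) {
  check_alignment(gold, predicted)
  types <- sort(unique(unlist(lapply(c(gold, predicted), function(s) {
    bieos_to_spans(s$tags)$type
  }), use.names = FALSE)))
  counts <- stats::setNames(
    rep(list(list(tp = 0L, gold = 0L, pred = 0L)), length(types)), types)
  for (i in seq_along(gold)) {
    gs <- bieos_to_spans(gold[[i]]$tags)
    ps <- bieos_to_spans(predicted[[i]]$tags)
    for (ty in types) {
      gk <- span_key(gs[gs$type == ty, , drop = FALSE])
      pk <- span_key(ps[ps$type == ty, , drop = FALSE])
      counts[[ty]]$tp <- counts[[ty]]$tp + match_exact(gk, pk)
      counts[[ty]]$gold <- counts[[ty]]$gold + length(gk)
      counts[[ty]]$pred <- counts[[ty]]$pred + length(pk)
    }
  }
  lapply(counts, function(cc) {
    new_eval_result(cc$tp, cc$pred - cc$tp, cc$gold - cc$tp)
  })
}

#' Format an evaluation report
#'
#' Renders overall and per-type results as aligned plain text or as
#' tab-separated records. Spans in reports are shown closed and 1-based.
#'
#' @param overall an `eval_result` from [score_corpus()].
#' @param by_type optional named list from [per_type_breakdown()].
#' @param format `"text"` or `"tsv"`.
#' @return character vector of report lines.
#' @export
format_eval_report <- function(overall, by_type = NULL,
                               format = c("text", "tsv")) {
  format <- match.arg(format)
  rows <- c(list(overall = overall), by_type)
  if (format == "tsv") {
    header <- paste(c("scope", "tp", "fp", "fn",
                      "precision", "recall", "f1"), collapse = "\t")
    body <- vapply(names(rows), function(nm) {
      x <- rows[[nm]]
      paste(c(nm, x$tp, x$fp, x$fn,
              sprintf("%.4f", c(x$precision, x$recall, x$f1))),
            collapse = "\t")
    }, character(1))
    return(c(header, body))
  }
  vapply(names(rows), function(nm) {
    x <- rows[[nm]]
    sprintf("%-12s TP %5d  FP %5d  FN %5d  P %.4f  R %.4f  F1 %.4f",
            nm, x$tp, x$fp, x$fn, x$precision, x$recall, x$f1)
  }, character(1))
}
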