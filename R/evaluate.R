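#' Confusion counts of a predicted edge set against ground truth
#'
#' Compares the predicted significant edges with the true differential edges
#' over the universe of candidate edges actually tested. Undirected (mode 1)
#' edges are compared after canonical (min, max) ordering; directed (mode 2)
#' edges are compared as ordered pairs. Predicted and truth edges must be
#' subsets of the universe.
#'
#' @param predicted Data frame of predicted edges (columns `source`,
#'   `target`), e.g. from [significant_edges()].
#' @param truth Data frame of true differential edges.
#' @param universe A `CandidateEdgeSet` (or data frame; assumed directed only
#'   if it carries attribute `directed = TRUE`).
#' @return A `ConfusionCounts` list with integer fields `tp`, `fp`, `tn`,
#'   `fn` summing to the universe size.
#' @export
edge_confusion <- function(predicted, truth, universe) {
  directed <- isTRUE(attr(universe, "directed"))
  uk <- .edge_key(universe, directed)
  if (anyDuplicated(uk)) stop("duplicate edges in universe")
  pk <- unique(.edge_key(predicted, directed))
  tk <- unique(.edge_key(truth, directed))
  bad_p <- setdiff(pk, uk)
  if (length(bad_p))
    stop("predicted edge(s) outside the candidate universe: ",
         paste(gsub("\r", " -> ", utils::head(bad_p, 5)), collapse = ", "))
  bad_t <- setdiff(tk, uk)
  if (length(bad_t))
    stop("truth edge(s) outside the candidate universe: ",
         paste(gsub("\r", " -> ", utils::head(bad_t, 5)), collapse = ", "))
  pred <- uk %in% pk
  tru <- uk %in% tk
  structure(list(tp = sum(pred & tru), fp = sum(pred & !tru),
                 tn = sum(!pred & !tru), fn = sum(!pred & tru)),
            class = "ConfusionCounts")
}

#' @export
print.ConfusionCounts <- function(x, ...) {
  cat(sprintf("ConfusionCounts: tp = %d, fp = %d, tn = %d, fn = %d (n = %d)\n",
              x$tp, x$fp, x$tn, x$fn, x$tp + x$fp + x$tn + x$fn))
  invisible(x)
}

#' Matthews correlation coefficient
#'
#' `(tp * tn - fp * fn) / sqrt((tp + fp)(tp + fn)(tn + fp)(tn + fn))`, a
#' balanced binary classification score in \[-1, 1\]: 1 for perfect
#' prediction, 0 for chance-level, -1 for total disagreement. When any factor
#' of the denominator is zero (e.g. nothing predicted), the value is defined
#' as 0.
#'
#' @param counts A `ConfusionCounts` object, or the `tp` count when the
#'   remaining counts are given separately.
#' @param fp,tn,fn Optional individual counts.
#' @return A single numeric value in \[-1, 1\].
#' @examples
#' mcc(3, 1, 4, 2)  # 10 / sqrt(600)
#' @export
mcc <- function(counts, fp = NULL, tn = NULL, fn = NULL) {
  if (inherits(counts, "ConfusionCounts")) {
    tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  } else {
    tp <- counts
    if (is.null(fp) || is.null(tn) || is.null(fn))
      stop("supply a ConfusionCounts object or all four counts")
  }
  if (any(c(tp, fp, tn, fn) < 0)) stop("counts must be non-negative")
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  # products can overflow integer range; compute in double
  (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(den)
}

#' Score a differential network against ground truth
#'
#' Convenience wrapper: extracts the significant edges of a pipeline result
#' under a rule, builds the confusion table over the tested candidate edges
#' and reports MCC, precision and recall.
#'
#' @param result A `dcnet_result`.
#' @param truth Data frame of true differential edges.
#' @param universe The `CandidateEdgeSet` the result was computed on.
#' @param rule Significance rule (defaults to the result's rule).
#' @return List with `counts` (`ConfusionCounts`), `mcc`, `precision`,
#'   `recall`.
#' @export
evaluate_network <- function(result, truth, universe, rule = NULL) {
  pred <- significant_edges(result, rule = rule)
  cc <- edge_confusion(pred, truth, universe)
  prec <- if (cc$tp + cc$fp == 0) NA_real_ else cc$tp / (cc$tp + cc$fp)
  rec <- if (cc$tp + cc$fn == 0) NA_real_ else cc$tp / (cc$tp + cc$fn)
  list(counts = cc, mcc = mcc(cc), precision = prec, recall = rec)
}
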