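#' Absolute difference in co-expression
#'
#' The first differential metric: the magnitude of change in association
#' between the two conditions, `|r_a - r_b|`. For correlation metrics it lies
#' in \[0, 2\]; 0 means no change, 2 a full sign flip between perfect
#' correlations.
#'
#' @param r_a,r_b Association values under conditions A and B.
#' @return Non-negative numeric (vectorized).
#' @export
delta_r <- function(r_a, r_b) abs(r_a - r_b)

#' Degree of association shift
#'
#' The second differential metric, combining the pooled-sample association
#' `r_ab` with the per-condition associations. The `"standard"` form is
#' `s = r_ab - 2 * (r_a + r_b)`. Because condition-driven mean shifts distort
#' the pooled association while leaving the per-condition associations
#' untouched, `s` responds to rewiring caused by differential expression,
#' which `|r_a - r_b|` alone cannot see.
#'
#' The `"centered"` form, `s = r_ab - (r_a + r_b) / 2`, subtracts the *mean*
#' of the per-condition associations, so it is zero for any edge whose pooled
#' association equals its average within-condition association, however
#' strongly co-expressed. It is offered as an alternative because the standard
#' form is dominated by `-2 (r_a + r_b)` and therefore also flags strong but
#' unchanged co-expression; see the package vignette for a discussion.
#'
#' @param r_ab Association over the pooled samples of both conditions.
#' @param r_a,r_b Per-condition association values.
#' @param form `"standard"` (default) or `"centered"`.
#' @return Numeric (vectorized).
#' @export
shift_s <- function(r_ab, r_a, r_b, form = c("standard", "centered")) {
  form <- match.arg(form)
  if (form == "standard") r_ab - 2 * (r_a + r_b) else r_ab - (r_a + r_b) / 2
}

.correction_aliases <- c(fdr_bh = "BH", bh = "BH", BH = "BH",
                         fdr_by = "BY", by = "BY", BY = "BY",
                         bonferroni = "bonferroni", holm = "holm",
                         hochberg = "hochberg", hommel = "hommel",
                         none = "none")

#' Multiple-testing correction across the tested edge family
#'
#' Adjusts a vector of raw empirical p-values, by default with the
#' Benjamini-Hochberg step-up false discovery rate procedure, and flags
#' significance at `adjusted < alpha`. The two differential metric families
#' (delta_r and s) are corrected separately, each across all tested edges.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @param method Correction method: `"fdr_bh"`/`"BH"` (default),
#'   `"bonferroni"`, `"holm"`, `"hochberg"`, `"hommel"`, `"fdr_by"`/`"BY"` or
#'   `"none"`.
#' @param alpha Significance threshold on the adjusted p-values (default
#'   0.01, applied strictly: significant means `padj < alpha`).
#' @return List with `padj` (adjusted p-values) and `sig` (logical).
#' @export
adjust_pvalues <- function(p, method = "fdr_bh", alpha = 0.01) {
  if (!method %in% names(.correction_aliases))
    stop("unknown correction method '", method, "'; supported: ",
         paste(unique(names(.correction_aliases)), collapse = ", "))
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  padj <- stats::p.adjust(p, method = .correction_aliases[[method]])
  list(padj = padj, sig = padj < alpha)
}

.apply_rule <- function(edges, rule) {
  switch(rule,
         deltar = edges$sig_delta_r,
         s      = edges$sig_s,
         either = edges$sig_delta_r | edges$sig_s,
         both   = edges$sig_delta_r & edges$sig_s,
         stop("unknown significance rule '", rule,
              "'; supported: deltar, s, either, both"))
}

#' Infer a differential (co-expression or regulatory) network
#'
#' The full pipeline: (1) fix the candidate edges (all gene pairs in mode 1,
#' or a supplied regulator-target prior in mode 2); (2) build one pooled
#' permutation background model for the two differential metrics; (3) score
#' every candidate edge — per-condition and pooled associations, absolute
#' difference in co-expression (right-tailed test) and association shift
#' (two-tailed test) with empirical p-values from the shared background;
#' (4) correct each metric family for multiple testing and flag significant
#' edges. The run is fully deterministic given `seed`.
#'
#' @param dataset An `ExpressionDataset` with two-level conditions.
#' @param candidates Optional `CandidateEdgeSet`; defaults to all unordered
#'   gene pairs (mode 1). Pass the result of [read_grn()] /
#'   [candidate_edges()] with a GRN for mode 2.
#' @inheritParams build_background
#' @param alpha Adjusted-p-value threshold (default 0.01).
#' @param correction Multiple-testing correction method; see
#'   [adjust_pvalues()].
#' @param rule Which metric decides significance when extracting the final
#'   network: `"either"` (default), `"deltar"`, `"s"` or `"both"`. Both
#'   families are always computed; the rule only filters at output time.
#' @param bins Bin count for the entropy metric, or `"auto"`.
#' @return A `dcnet_result`: list with `edges` (data frame, one row per
#'   tested edge: source, target, r_a, r_b, r_ab, delta_r, s, p_delta_r, p_s,
#'   padj_delta_r, padj_s, sig_delta_r, sig_s, degenerate), `background`,
#'   and the run parameters. Degenerate (zero-variance) edges are reported
#'   with p = 1 and flagged, not dropped.
#' @seealso [significant_edges()], [write_network()]
#' @examples
#' bm <- simulate_benchmark(n_tf = 3, n_tg = 9, m_samples = 40,
#'                          perturbation = "loss_of_coexpr", seed = 1)
#' res <- run_dcnet(bm$dataset, candidate_edges(bm$dataset, bm$network),
#'                  n_perm = 200, seed = 1)
#' res
#' @export
run_dcnet <- function(dataset, candidates = NULL,
                      metric = c("pearson", "spearman", "entropy"),
                      n_perm = 10000, seed = 42, alpha = 0.01,
                      correction = "fdr_bh",
                      rule = c("either", "deltar", "s", "both"),
                      s_form = c("standard", "centered"),
                      bins = "auto") {
  metric <- match.arg(metric)
  rule <- match.arg(rule)
  s_form <- match.arg(s_form)
  stopifnot(inherits(dataset, "ExpressionDataset"))
  if (is.null(dataset$conditions)) stop("dataset has no condition annotation")
  if (is.null(candidates)) candidates <- candidate_edges(dataset)
  E <- nrow(candidates)
  if (is.null(E) || E == 0) stop("candidate edge set is empty")

  bg <- build_background(dataset, candidates, metric = metric,
                         n_perm = n_perm, seed = seed, s_form = s_form)

  vals <- dataset$values
  ia <- dataset$conditions == levels(dataset$conditions)[1]
  afun <- .assoc_fun(metric)
  src <- match(candidates$source, rownames(vals))
  tgt <- match(candidates$target, rownames(vals))
  r_a <- r_b <- r_ab <- numeric(E)
  degen <- logical(E)
  for (i in seq_len(E)) {
    x <- vals[src[i], ]
    y <- vals[tgt[i], ]
    r_a[i]  <- afun(x[ia], y[ia])
    r_b[i]  <- afun(x[!ia], y[!ia])
    r_ab[i] <- afun(x, y)
    degen[i] <- .zero_var(x[ia]) || .zero_var(y[ia]) ||
      .zero_var(x[!ia]) || .zero_var(y[!ia])
  }
  dr <- delta_r(r_a, r_b)
  sv <- shift_s(r_ab, r_a, r_b, form = s_form)
  p_dr <- empirical_p(dr, bg, which = "delta_r")
  p_s <- empirical_p(sv, bg, which = "s")
  p_dr[degen] <- 1
  p_s[degen] <- 1
  adj_dr <- adjust_pvalues(p_dr, method = correction, alpha = alpha)
  adj_s <- adjust_pvalues(p_s, method = correction, alpha = alpha)

  edges <- data.frame(source = candidates$source, target = candidates$target,
                      r_a = r_a, r_b = r_b, r_ab = r_ab,
                      delta_r = dr, s = sv,
                      p_delta_r = p_dr, p_s = p_s,
                      padj_delta_r = adj_dr$padj, padj_s = adj_s$padj,
                      sig_delta_r = adj_dr$sig, sig_s = adj_s$sig,
                      degenerate = degen,
                      stringsAsFactors = FALSE)
  structure(list(edges = edges, background = bg,
                 mode = attr(candidates, "mode") %||% 1L,
                 directed = isTRUE(attr(candidates, "directed")),
                 metric = metric, alpha = alpha, correction = correction,
                 n_perm = bg$n_perm, seed = seed, rule = rule,
                 s_form = s_form, bins = bins,
                 conditions = levels(dataset$conditions)),
            class = "dcnet_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract the significant differential network
#'
#' @param result A `dcnet_result`.
#' @param rule Significance rule; defaults to the rule stored in the result.
#' @return Data frame of edges passing the rule.
#' @export
significant_edges <- function(result, rule = NULL) {
  stopifnot(inherits(result, "dcnet_result"))
  rule <- rule %||% result$rule
  result$edges[.apply_rule(result$edges, rule), , drop = FALSE]
}

#' @export
print.dcnet_result <- function(x, ...) {
  e <- x$edges
  cat(sprintf("Differential network (mode %d, %s, metric = %s)\n",
              x$mode, if (x$directed) "directed" else "undirected", x$metric))
  cat(sprintf("  %d edges tested | background: %d permutations, seed %s\n",
              nrow(e), x$n_perm, format(x$seed)))
  cat(sprintf("  significant at padj < %g (%s): delta_r %d, s %d, either %d, both %d\n",
              x$alpha, x$correction,
              sum(e$sig_delta_r), sum(e$sig_s),
              sum(e$sig_delta_r | e$sig_s), sum(e$sig_delta_r & e$sig_s)))
  if (any(e$degenerate))
    cat(sprintf("  %d edge(s) flagged degenerate (zero variance)\n",
                sum(e$degenerate)))
  invisible(x)
}
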