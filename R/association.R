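# Association measures. Internal .assoc_* functions assume validated numeric
# input and are kept allocation-light: they sit in the permutation inner loop.

.zero_var <- function(v) {
  r <- range(v)
  r[1] == r[2]
}

.assoc_pearson <- function(x, y) {
  if (.zero_var(x) || .zero_var(y)) return(0)
  stats::cor(x, y)
}

.assoc_spearman <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  if (.zero_var(rx) || .zero_var(ry)) return(0)
  stats::cor(rx, ry)
}

.auto_bins <- function(n) max(2L, floor(sqrt(n)))

# Signed normalized mutual information on equal-frequency bins.
# Bin by average-tie ranks so the measure is invariant under strictly
# increasing transforms; magnitude I/sqrt(H(X)H(Y)) in [0,1]; sign from
# Spearman correlation.
.assoc_entropy <- function(x, y, bins = "auto") {
  n <- length(x)
  B <- if (identical(bins, "auto")) .auto_bins(n) else as.integer(bins)
  rx <- rank(x)
  ry <- rank(y)
  bx <- ceiling(rx * B / n)
  by <- ceiling(ry * B / n)
  bx[bx < 1L] <- 1L; bx[bx > B] <- B
  by[by < 1L] <- 1L; by[by > B] <- B
  px <- tabulate(bx, B) / n
  py <- tabulate(by, B) / n
  pj <- tabulate(bx + B * (by - 1L), B * B) / n
  hx <- -sum(px[px > 0] * log(px[px > 0]))
  hy <- -sum(py[py > 0] * log(py[py > 0]))
  hj <- -sum(pj[pj > 0] * log(pj[pj > 0]))
  den <- sqrt(hx * hy)
  if (den == 0) return(0)
  m <- min(1, max(0, (hx + hy - hj) / den))
  rs <- if (.zero_var(rx) || .zero_var(ry)) 0 else stats::cor(rx, ry)
  if (rs > 0) m else if (rs < 0) -m else 0
}

.assoc_fun <- function(metric) {
  switch(metric,
         pearson  = .assoc_pearson,
         spearman = .assoc_spearman,
         entropy  = .assoc_entropy,
         stop("unknown association metric '", metric,
              "'; supported: pearson, spearman, entropy"))
}

.validate_xy <- function(x, y) {
  if (length(x) != length(y))
    stop("x and y must have equal length (got ", length(x), " and ", length(y), ")")
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("non-finite values in input vectors")
}

#' Gene-pair association under a selectable metric
#'
#' Computes the association between two expression vectors using one of three
#' measures: Pearson product-moment correlation, Spearman rank correlation
#' (average ranks for ties), or a signed normalized mutual information
#' ("entropy") measure. All three return values in \[-1, 1\].
#'
#' @details The entropy measure discretizes each vector separately into `bins`
#' equal-frequency bins via average-tie ranks (default `"auto"` =
#' `max(2, floor(sqrt(n)))`), computes the mutual information I(X;Y) and the
#' marginal entropies H(X), H(Y) of the binned variables in nats, and returns
#' `sign(spearman(x, y)) * I / sqrt(H(X) * H(Y))` (0 when `H(X) * H(Y) = 0`).
#' It quantifies how far the joint expression distribution departs from
#' independence and, unlike the correlation measures, is sensitive to
#' non-monotone dependence; equal-frequency binning makes it invariant under
#' strictly increasing transforms of either argument.
#'
#' If either vector has zero variance the association is defined as 0 and the
#' result carries attribute `degenerate = TRUE`, so downstream code can flag
#' (rather than drop) such edges.
#'
#' @param x,y Numeric vectors of equal length (>= 3), finite.
#' @param metric `"pearson"`, `"spearman"` or `"entropy"`.
#' @param bins Bin count for the entropy measure, or `"auto"`.
#' @return A single association value in \[-1, 1\] with logical attribute
#'   `degenerate`.
#' @examples
#' association(1:10, (1:10)^2, metric = "spearman")  # 1: monotone
#' association(c(1, 2, 3, 4), c(9, 7, 5, 3), metric = "pearson")  # -1
#' @export
association <- function(x, y, metric = c("pearson", "spearman", "entropy"),
                        bins = "auto") {
  metric <- match.arg(metric)
  .validate_xy(x, y)
  if (metric == "entropy") {
    n <- length(x)
    B <- if (identical(bins, "auto")) .auto_bins(n) else as.integer(bins)
    if (B > n) stop("bins (", B, ") cannot exceed the number of observations (", n, ")")
    if (B < 2) stop("bins must be >= 2")
    v <- .assoc_entropy(x, y, bins = B)
  } else {
    v <- .assoc_fun(metric)(x, y)
  }
  attr(v, "degenerate") <- .zero_var(x) || .zero_var(y)
  v
}

#' Per-condition and pooled association for one gene pair
#'
#' Computes the association triple (r_a, r_b, r_ab) for a candidate edge:
#' r_a over the samples of the first condition, r_b over the second, and r_ab
#' over all samples pooled, all under the same metric. These are the inputs of
#' the two differential metrics ([delta_r()] and [shift_s()]).
#'
#' @param dataset An `ExpressionDataset` with conditions set.
#' @param pair Character vector of two gene ids (source, target).
#' @inheritParams association
#' @return A list of class `AssociationTriple` with elements `r_a`, `r_b`,
#'   `r_ab`, `metric`, `conditions` (the two labels, in factor-level order)
#'   and `degenerate`.
#' @export
association_triple <- function(dataset, pair,
                               metric = c("pearson", "spearman", "entropy"),
                               bins = "auto") {
  metric <- match.arg(metric)
  stopifnot(inherits(dataset, "ExpressionDataset"))
  if (is.null(dataset$conditions)) stop("dataset has no condition annotation")
  pair <- as.character(pair)
  absent <- setdiff(pair, rownames(dataset$values))
  if (length(absent)) stop("gene(s) not in dataset: ", paste(absent, collapse = ", "))
  lv <- levels(dataset$conditions)
  ia <- dataset$conditions == lv[1]
  x <- dataset$values[pair[1], ]
  y <- dataset$values[pair[2], ]
  r_a  <- association(x[ia], y[ia], metric = metric, bins = bins)
  r_b  <- association(x[!ia], y[!ia], metric = metric, bins = bins)
  r_ab <- association(x, y, metric = metric, bins = bins)
  structure(list(r_a = as.numeric(r_a), r_b = as.numeric(r_b),
                 r_ab = as.numeric(r_ab), metric = metric, conditions = lv,
                 degenerate = attr(r_a, "degenerate") ||
                   attr(r_b, "degenerate") || attr(r_ab, "degenerate")),
            class = "AssociationTriple")
}

#' @export
print.AssociationTriple <- function(x, ...) {
  cat(sprintf("AssociationTriple (%s): r_%s = %.4f, r_%s = %.4f, r_pooled = %.4f%s\n",
              x$metric, x$conditions[1], x$r_a, x$conditions[2], x$r_b, x$r_ab,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}
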