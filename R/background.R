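# Pooled permutation background model.
#
# One null draw: shuffle each gene's values within each condition (keeps the
# per-condition marginals, destroys the gene-gene coupling) to get r~_a, r~_b,
# and shuffle both genes' pooled vectors across all samples to get r~_ab. The
# null differential metrics are then formed exactly as for observed edges.
# A single model of N_p such draws, sampled over the candidate edges, serves
# every tested edge.

.permute_pair_null <- function(xA, xB, yA, yB, afun, s_form) {
  nA <- length(xA); nB <- length(xB)
  pa <- afun(xA[sample.int(nA)], yA[sample.int(nA)])
  pb <- afun(xB[sample.int(nB)], yB[sample.int(nB)])
  x <- c(xA, xB); y <- c(yA, yB)
  n <- nA + nB
  pab <- afun(x[sample.int(n)], y[sample.int(n)])
  c(abs(pa - pb), shift_s(pab, pa, pb, form = s_form))
}

#' One permutation draw from the null of the differential metrics
#'
#' Shuffles the two genes' expression values independently within each
#' condition (computing the null per-condition associations) and across the
#' pooled samples (computing the null pooled association), then returns the
#' null absolute difference in co-expression and null association shift.
#' Uses the current RNG state; seed with [set.seed()] for reproducibility.
#'
#' @inheritParams association_triple
#' @param s_form Which form of the shift metric to use; see [shift_s()].
#' @return Named numeric vector `c(delta_r = ..., s = ...)`.
#' @export
permute_once <- function(dataset, pair,
                         metric = c("pearson", "spearman", "entropy"),
                         s_form = c("standard", "centered")) {
  metric <- match.arg(metric)
  s_form <- match.arg(s_form)
  stopifnot(inherits(dataset, "ExpressionDataset"))
  if (is.null(dataset$conditions)) stop("dataset has no condition annotation")
  pair <- as.character(pair)
  absent <- setdiff(pair, rownames(dataset$values))
  if (length(absent)) stop("gene(s) not in dataset: ", paste(absent, collapse = ", "))
  ia <- dataset$conditions == levels(dataset$conditions)[1]
  x <- dataset$values[pair[1], ]
  y <- dataset$values[pair[2], ]
  v <- .permute_pair_null(x[ia], x[!ia], y[ia], y[!ia], .assoc_fun(metric), s_form)
  c(delta_r = v[1], s = v[2])
}

#' Build the pooled permutation background model
#'
#' Draws `n_perm` null values of both differential metrics. Each draw picks
#' one candidate edge uniformly at random (with replacement), so the null
#' reflects the marginal distributions of the genes actually tested, and
#' applies the within-condition / pooled shuffling scheme of [permute_once()].
#' The resulting model is shared by all tested edges, replacing the much more
#' expensive per-edge permutation null.
#'
#' @param dataset An `ExpressionDataset` with conditions set.
#' @param candidates A `CandidateEdgeSet` (see [candidate_edges()]).
#' @inheritParams permute_once
#' @param n_perm Number of permutations N_p (default 10000; fewer than 1000
#'   triggers a warning, fewer than 100 an error-level warning about
#'   resolution of the empirical p-values).
#' @param seed Integer seed; the model is fully reproducible given the seed,
#'   dataset and candidate set.
#' @return A `BackgroundModel`: list with numeric vectors `null_delta_r`,
#'   `null_s` (length `n_perm`), plus `n_perm`, `metric`, `s_form`, `seed`.
#' @export
build_background <- function(dataset, candidates,
                             metric = c("pearson", "spearman", "entropy"),
                             n_perm = 10000, seed = 42,
                             s_form = c("standard", "centered")) {
  metric <- match.arg(metric)
  s_form <- match.arg(s_form)
  stopifnot(inherits(dataset, "ExpressionDataset"))
  if (is.null(dataset$conditions)) stop("dataset has no condition annotation")
  if (is.null(nrow(candidates)) || nrow(candidates) == 0)
    stop("candidate edge set is empty")
  n_perm <- as.integer(n_perm)
  if (is.na(n_perm) || n_perm < 1) stop("n_perm must be a positive integer")
  if (n_perm < 100)
    warning("n_perm < 100 gives very coarse empirical p-values")
  else if (n_perm < 1000)
    warning("n_perm < 1000; at least 1000 permutations are recommended")
  set.seed(seed)
  afun <- .assoc_fun(metric)
  vals <- dataset$values
  ia <- dataset$conditions == levels(dataset$conditions)[1]
  src <- match(candidates$source, rownames(vals))
  tgt <- match(candidates$target, rownames(vals))
  E <- length(src)
  pick <- sample.int(E, n_perm, replace = TRUE)
  nd <- numeric(n_perm)
  ns <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    x <- vals[src[pick[i]], ]
    y <- vals[tgt[pick[i]], ]
    v <- .permute_pair_null(x[ia], x[!ia], y[ia], y[!ia], afun, s_form)
    nd[i] <- v[1]
    ns[i] <- v[2]
  }
  structure(list(null_delta_r = nd, null_s = ns, n_perm = n_perm,
                 metric = metric, s_form = s_form, seed = seed),
            class = "BackgroundModel")
}

#' @export
print.BackgroundModel <- function(x, ...) {
  cat(sprintf("BackgroundModel: %d permutations, metric = %s, seed = %s\n",
              x$n_perm, x$metric, format(x$seed)))
  cat(sprintf("  null delta_r: median %.4f, 99%% %.4f\n",
              stats::median(x$null_delta_r),
              stats::quantile(x$null_delta_r, 0.99)))
  cat(sprintf("  null s: median %.4f, spread (sd) %.4f\n",
              stats::median(x$null_s), stats::sd(x$null_s)))
  invisible(x)
}

#' Empirical p-values from the background model
#'
#' Converts observed differential metric values into empirical p-values
#' against the pooled null. The test for the absolute difference in
#' co-expression is right-tailed:
#' `p = (1 + #\{null >= obs\}) / (1 + N_p)`. The test for the shift metric is
#' two-tailed: twice the smaller of the left and right tail probabilities
#' (each with the same +1 pseudocount), capped at 1. The pseudocount
#' guarantees p in (0, 1].
#'
#' @param observed Numeric vector of observed metric values.
#' @param model A `BackgroundModel`.
#' @param which `"delta_r"` or `"s"` — which null to test against.
#' @return Numeric vector of p-values, same length as `observed`.
#' @export
empirical_p <- function(observed, model, which = c("delta_r", "s")) {
  which <- match.arg(which)
  stopifnot(inherits(model, "BackgroundModel"))
  np <- model$n_perm
  if (which == "delta_r") {
    srt <- sort(model$null_delta_r)
    n_ge <- np - findInterval(observed, srt, left.open = TRUE)
    (1 + n_ge) / (1 + np)
  } else {
    srt <- sort(model$null_s)
    n_le <- findInterval(observed, srt)
    n_ge <- np - findInterval(observed, srt, left.open = TRUE)
    pmin(1, 2 * pmin((1 + n_le) / (1 + np), (1 + n_ge) / (1 + np)))
  }
}
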