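# Independent reference implementations and fixture builders used as oracles.
# These deliberately avoid the package's own code paths.

# all permutations of 1..n (n small), one per row
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (pos in seq_len(n)) {
    blk <- cbind(sub, n)
    if (pos < n) blk <- blk[, c(seq_len(pos - 1L), n, pos:(n - 1L)), drop = FALSE]
    out[r + seq_len(nrow(sub)), ] <- blk
    r <- r + nrow(sub)
  }
  out
}

# Benjamini-Hochberg step-up, written directly from the definition
bh_step_up <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  running <- Inf
  for (i in n:1) {
    running <- min(running, p[o[i]] * n / i)
    adj[o[i]] <- min(1, running)
  }
  adj
}

# MCC as the Pearson correlation of the two binary indicator vectors
mcc_as_cor <- function(tp, fp, tn, fn) {
  pred <- c(rep(1, tp), rep(1, fp), rep(0, tn), rep(0, fn))
  tru <- c(rep(1, tp), rep(0, fp), rep(0, tn), rep(1, fn))
  if (length(unique(pred)) < 2 || length(unique(tru)) < 2) return(0)
  stats::cor(pred, tru)
}

# small expression dataset fixture built in code
make_dataset <- function(values, n_a, n_b, genes = NULL) {
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(values)))
  m <- n_a + n_b
  samples <- paste0("s", seq_len(m))
  dimnames(values) <- list(genes, samples)
  suppressWarnings(expression_dataset(
    values, stats::setNames(rep(c("A", "B"), c(n_a, n_b)), samples)))
}

# dataset with a planted differentially co-expressed pair among iid decoys:
# the pair is r-correlated in condition A and (-r)-correlated in B
make_planted_dataset <- function(n_decoys, n_a, n_b, r = 0.9, seed = 1) {
  set.seed(seed)
  m <- n_a + n_b
  x <- stats::rnorm(m)
  e <- stats::rnorm(m)
  y <- numeric(m)
  y[1:n_a] <- r * x[1:n_a] + sqrt(1 - r^2) * e[1:n_a]
  y[(n_a + 1):m] <- -r * x[(n_a + 1):m] + sqrt(1 - r^2) * e[(n_a + 1):m]
  vals <- rbind(x, y, matrix(stats::rnorm(n_decoys * m), n_decoys, m))
  make_dataset(vals, n_a, n_b,
               genes = c("gx", "gy", sprintf("d%02d", seq_len(n_decoys))))
}
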