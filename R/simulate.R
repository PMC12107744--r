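# Benchmarking simulator: tree-shaped TF->TG network, multivariate-normal
# expression with correlations decaying along graph paths, case-group
# perturbations, and a ground-truth differential edge set.

.gene_names <- function(prefix, n) {
  sprintf(paste0(prefix, "%0", max(2L, nchar(n)), "d"), seq_len(n))
}

#' Generate a random tree-shaped regulatory network
#'
#' Grows a tree over `n_tf` transcription factors and `n_tg` target genes by
#' attaching each new node to a uniformly chosen existing TF. TFs are added
#' first, so TFs may regulate both TFs and TGs while TGs are always leaves.
#' Edges are directed parent (regulator) to child (target).
#'
#' @param n_tf,n_tg Number of transcription factors / target genes (>= 1).
#' @param seed Optional integer seed.
#' @return A `tree_grn`: data frame with columns `source`, `target`
#'   (`n_tf + n_tg - 1` edges) and attributes `tf`, `tg` (gene id vectors).
#' @export
simulate_tree_grn <- function(n_tf, n_tg, seed = NULL) {
  stopifnot(n_tf >= 1, n_tg >= 1)
  if (!is.null(seed)) set.seed(seed)
  tf <- .gene_names("TF", n_tf)
  tg <- .gene_names("TG", n_tg)
  nodes <- c(tf, tg)
  n <- length(nodes)
  parent <- integer(n)  # index into nodes; 0 for the root
  for (i in seq_len(n)[-1]) {
    # candidate parents: TFs already in the tree
    k <- min(i - 1L, n_tf)
    parent[i] <- if (k == 1L) 1L else sample.int(k, 1L)
  }
  edges <- data.frame(source = nodes[parent[-1]], target = nodes[-1],
                      stringsAsFactors = FALSE)
  structure(edges, tf = tf, tg = tg,
            class = c("tree_grn", "data.frame"))
}

.grn_genes <- function(grn) {
  if (inherits(grn, "tree_grn")) c(attr(grn, "tf"), attr(grn, "tg"))
  else unique(c(grn$source, grn$target))
}

.grn_graph <- function(grn) {
  genes <- .grn_genes(grn)
  igraph::graph_from_data_frame(grn[, c("source", "target")],
                                directed = FALSE, vertices = genes)
}

#' Path-distance correlation matrix of a gene network
#'
#' Translates a connected tree into a correlation matrix with
#' `Sigma[i, j] = rho^d(i, j)`, where `d` is the shortest-path distance on
#' the undirected graph. For a tree and `rho` in (0, 1) this matrix is
#' symmetric positive definite, so it can be used directly as the correlation
#' of a multivariate normal expression model.
#'
#' @param grn A `tree_grn` (or any two-column edge list of a connected graph).
#' @param rho Base correlation between adjacent genes, in (0, 1).
#' @return Correlation matrix over the network's genes (unit diagonal).
#' @export
graph_covariance <- function(grn, rho) {
  if (!is.numeric(rho) || length(rho) != 1 || rho <= 0 || rho >= 1)
    stop("rho must be a single value in (0, 1)")
  g <- .grn_graph(grn)
  d <- igraph::distances(g)
  genes <- .grn_genes(grn)
  sig <- rho^d[genes, genes]
  diag(sig) <- 1
  sig
}

# Eigenvalue clipping to nearest positive definite, then rescale to unit
# diagonal. A no-op for matrices that are already valid correlations.
.repair_pd <- function(S, eps = 1e-8) {
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) >= eps) return(S)
  v <- pmax(e$values, eps)
  S2 <- e$vectors %*% (v * t(e$vectors))
  S2 <- stats::cov2cor(S2)
  dimnames(S2) <- dimnames(S)
  S2
}

#' Draw multivariate-normal expression data for a network
#'
#' Samples `m_samples` i.i.d. observations from
#' `MVN(mu * 1, sigma^2 * Sigma)` with `Sigma` the path-distance correlation
#' of the network ([graph_covariance()]). Genes are named from the network;
#' samples are `S001`, `S002`, ...
#'
#' @inheritParams graph_covariance
#' @param m_samples Number of samples (>= 4).
#' @param mu,sigma Mean and standard deviation of every gene's expression.
#' @param seed Optional integer seed.
#' @return An `ExpressionDataset` without condition annotation.
#' @export
simulate_expression <- function(grn, m_samples, rho = 0.8, mu = 6, sigma = 1,
                                seed = NULL) {
  stopifnot(m_samples >= 4)
  if (!is.null(seed)) set.seed(seed)
  sig <- graph_covariance(grn, rho)
  genes <- .grn_genes(grn)
  x <- MASS::mvrnorm(m_samples, mu = rep(mu, length(genes)),
                     Sigma = sigma^2 * sig)
  vals <- t(x)
  dimnames(vals) <- list(genes,
                         sprintf(paste0("S%0", max(3L, nchar(m_samples)), "d"),
                                 seq_len(m_samples)))
  expression_dataset(vals)
}

.perturbation_types <- c("knockdown", "diff_expr", "inversion", "loss_of_coexpr")

# TFs are sampled before TGs so perturbations sit upstream and propagate
# through regulation.
.select_perturbed <- function(grn, k) {
  tf <- attr(grn, "tf")
  tg <- attr(grn, "tg")
  if (k <= 0) return(character(0))
  if (k <= length(tf)) {
    sample(tf, k)
  } else {
    c(tf, sample(tg, min(k - length(tf), length(tg))))
  }
}

#' Case-group model under a perturbation
#'
#' Builds the mean vector and correlation matrix from which case samples are
#' drawn, given a set of perturbed genes and their per-gene perturbation
#' types:
#' \describe{
#'   \item{knockdown}{the gene's case mean is multiplied by
#'     `knockdown_factor` (< 1); correlations are untouched.}
#'   \item{diff_expr}{`de_shift` is added to the gene's case mean.}
#'   \item{inversion}{every network edge incident to the gene flips the sign
#'     of its correlation, and the sign change propagates to all pairs whose
#'     path runs through that edge (path-product of edge signs).}
#'   \item{loss_of_coexpr}{every incident edge is cut: pairs whose path runs
#'     through it become uncorrelated.}
#' }
#' The resulting matrix is repaired to the nearest positive definite
#' correlation matrix (eigenvalue clipping at 1e-8, then unit-diagonal
#' rescaling); for tree networks the sign-flip and cut constructions are
#' already positive definite and the repair is a no-op.
#'
#' @inheritParams graph_covariance
#' @param gene_types Named character vector: perturbed gene id -> type (one
#'   of `"knockdown"`, `"diff_expr"`, `"inversion"`, `"loss_of_coexpr"`).
#' @param mu,sigma Baseline mean and standard deviation.
#' @param knockdown_factor Multiplicative mean reduction in (0, 1).
#' @param de_shift Additive mean shift (default `2 * sigma`).
#' @return List with `mean` (named vector), `corr` (correlation matrix) and
#'   `gene_types`.
#' @export
perturbed_model <- function(grn, rho, gene_types, mu = 6, sigma = 1,
                            knockdown_factor = 0.1, de_shift = 2 * sigma) {
  if (knockdown_factor <= 0 || knockdown_factor >= 1)
    stop("knockdown_factor must lie in (0, 1)")
  genes <- .grn_genes(grn)
  bad <- setdiff(names(gene_types), genes)
  if (length(bad)) stop("perturbed gene(s) not in network: ",
                        paste(bad, collapse = ", "))
  bad_t <- setdiff(gene_types, .perturbation_types)
  if (length(bad_t)) stop("unknown perturbation type(s): ",
                          paste(bad_t, collapse = ", "))
  mean_case <- stats::setNames(rep(mu, length(genes)), genes)
  kd <- names(gene_types)[gene_types == "knockdown"]
  de <- names(gene_types)[gene_types == "diff_expr"]
  mean_case[kd] <- mean_case[kd] * knockdown_factor
  mean_case[de] <- mean_case[de] + de_shift
  inv <- names(gene_types)[gene_types == "inversion"]
  loc <- names(gene_types)[gene_types == "loss_of_coexpr"]

  g <- .grn_graph(grn)
  d <- igraph::distances(g)[genes, genes]
  corr <- rho^d
  if (length(inv) || length(loc)) {
    flip <- grn$source %in% inv | grn$target %in% inv
    cut <- grn$source %in% loc | grn$target %in% loc
    # z[i] = product of edge signs on the root path; path sign = z_i * z_j
    gs <- igraph::graph_from_data_frame(
      grn[, c("source", "target")], directed = FALSE,
      vertices = data.frame(name = genes))
    igraph::E(gs)$nflip <- as.numeric(flip)
    dneg <- igraph::distances(gs, v = genes[1], weights = igraph::E(gs)$nflip)
    z <- stats::setNames((-1)^dneg[1, genes], genes)
    corr <- corr * (z %o% z)
    if (any(cut)) {
      gcut <- igraph::delete_edges(gs, which(cut))
      comp <- igraph::components(gcut)$membership[genes]
      corr[outer(comp, comp, "!=")] <- 0
    }
  }
  diag(corr) <- 1
  corr <- .repair_pd(corr)
  list(mean = mean_case, corr = corr, gene_types = gene_types)
}

#' Simulate a full case/control benchmark with known differential edges
#'
#' End-to-end generator for benchmarking differential co-expression methods:
#' \enumerate{
#'   \item grow a tree-shaped TF->TG network ([simulate_tree_grn()]);
#'   \item draw control samples from `MVN(mu, sigma^2 * rho^d)`;
#'   \item pick `round(perturb_fraction * n_genes)` perturbed genes (TFs
#'     first, so perturbations propagate through regulation) and draw the
#'     case samples from the perturbed model ([perturbed_model()]);
#'   \item add i.i.d. Gaussian noise `N(0, noise_sd^2)` to every entry of
#'     both groups;
#'   \item record the ground truth: every network edge incident to at least
#'     one perturbed gene is truly differential.
#' }
#' `perturbation = "mixed"` assigns each perturbed gene one of the four types
#' uniformly at random; `"none"` draws the case group from the unperturbed
#' model (a null benchmark: case and control are exchangeable).
#'
#' @param n_tf,n_tg Network size (default 20 TFs, 80 TGs).
#' @param m_samples Total number of samples (default 100).
#' @param case_ratio Fraction of samples assigned to the case group, in
#'   (0, 1); both groups must end up with >= 2 samples.
#' @param perturbation One of `"knockdown"`, `"diff_expr"`, `"inversion"`,
#'   `"loss_of_coexpr"`, `"mixed"`, `"none"`.
#' @param perturb_fraction Fraction of genes perturbed, in (0, 1).
#' @param rho Base correlation of adjacent genes (default 0.8).
#' @param mu,sigma Baseline expression mean and standard deviation (defaults
#'   6 and 1, arbitrary normalized units).
#' @param noise_sd Standard deviation of the additive Gaussian measurement
#'   noise (default 0.1).
#' @param knockdown_factor,de_shift Perturbation magnitudes; see
#'   [perturbed_model()].
#' @param seed Optional integer seed; the whole benchmark is reproducible.
#' @return A `SimulatedBenchmark`: list with `network` (`tree_grn`),
#'   `dataset` (`ExpressionDataset`, conditions `control`/`case`),
#'   `truth_edges` (data frame), `perturbed_genes`, `gene_types`,
#'   `perturbation` and `params`.
#' @export
simulate_benchmark <- function(n_tf = 20, n_tg = 80, m_samples = 100,
                               case_ratio = 0.5,
                               perturbation = c("knockdown", "diff_expr",
                                                "inversion", "loss_of_coexpr",
                                                "mixed", "none"),
                               perturb_fraction = 0.1,
                               rho = 0.8, mu = 6, sigma = 1, noise_sd = 0.1,
                               knockdown_factor = 0.1, de_shift = 2 * sigma,
                               seed = NULL) {
  perturbation <- match.arg(perturbation)
  if (case_ratio <= 0 || case_ratio >= 1)
    stop("case_ratio must lie in (0, 1)")
  if (perturbation != "none" &&
      (perturb_fraction <= 0 || perturb_fraction >= 1))
    stop("perturb_fraction must lie in (0, 1)")
  if (!is.null(seed)) set.seed(seed)

  grn <- simulate_tree_grn(n_tf, n_tg)
  genes <- .grn_genes(grn)
  n_case <- round(case_ratio * m_samples)
  n_ctrl <- m_samples - n_case
  if (n_case < 2 || n_ctrl < 2)
    stop("both groups need >= 2 samples (got control = ", n_ctrl,
         ", case = ", n_case, ")")

  sig0 <- graph_covariance(grn, rho)
  ctrl <- t(MASS::mvrnorm(n_ctrl, mu = rep(mu, length(genes)),
                          Sigma = sigma^2 * sig0))

  if (perturbation == "none") {
    perturbed <- character(0)
    gene_types <- stats::setNames(character(0), character(0))
    model <- list(mean = stats::setNames(rep(mu, length(genes)), genes),
                  corr = sig0)
  } else {
    k <- round(perturb_fraction * length(genes))
    perturbed <- .select_perturbed(grn, k)
    types <- if (perturbation == "mixed")
      sample(.perturbation_types, length(perturbed), replace = TRUE)
    else rep(perturbation, length(perturbed))
    gene_types <- stats::setNames(types, perturbed)
    model <- perturbed_model(grn, rho, gene_types, mu = mu, sigma = sigma,
                             knockdown_factor = knockdown_factor,
                             de_shift = de_shift)
  }
  case <- t(MASS::mvrnorm(n_case, mu = model$mean[genes],
                          Sigma = sigma^2 * model$corr))
  vals <- cbind(ctrl, case)
  vals <- vals + matrix(stats::rnorm(length(vals), 0, noise_sd), nrow(vals))
  samples <- sprintf(paste0("S%0", max(3L, nchar(m_samples)), "d"),
                     seq_len(m_samples))
  dimnames(vals) <- list(genes, samples)
  cond <- stats::setNames(rep(c("control", "case"), c(n_ctrl, n_case)),
                          samples)
  ds <- suppressWarnings(expression_dataset(vals, cond))

  truth <- grn[grn$source %in% perturbed | grn$target %in% perturbed,
               c("source", "target"), drop = FALSE]
  rownames(truth) <- NULL
  structure(list(network = grn, dataset = ds, truth_edges = truth,
                 perturbed_genes = perturbed, gene_types = gene_types,
                 perturbation = perturbation,
                 params = list(n_tf = n_tf, n_tg = n_tg,
                               m_samples = m_samples, case_ratio = case_ratio,
                               perturb_fraction = perturb_fraction, rho = rho,
                               mu = mu, sigma = sigma, noise_sd = noise_sd,
                               knockdown_factor = knockdown_factor,
                               de_shift = de_shift, seed = seed)),
            class = "SimulatedBenchmark")
}

#' @export
print.SimulatedBenchmark <- function(x, ...) {
  cat(sprintf("SimulatedBenchmark: %s perturbation\n", x$perturbation))
  cat(sprintf("  network: %d TFs + %d TGs, %d edges\n",
              length(attr(x$network, "tf")), length(attr(x$network, "tg")),
              nrow(x$network)))
  tab <- table(x$dataset$conditions)
  cat(sprintf("  samples: %s\n",
              paste(sprintf("%s (n=%d)", names(tab), tab), collapse = ", ")))
  cat(sprintf("  perturbed genes: %d | truth edges: %d\n",
              length(x$perturbed_genes), nrow(x$truth_edges)))
  invisible(x)
}

#' Homogeneous null dataset
#'
#' Generates expression data with no condition difference and no gene-gene
#' dependence: every gene is drawn i.i.d. `N(mu, sigma^2)` across all
#' samples, and samples are split into two labeled groups. Running the
#' differential pipeline on such data is a pure null experiment, useful for
#' checking type-I error control.
#'
#' @param n_genes Number of genes.
#' @param n_a,n_b Samples per condition (labels `"A"`, `"B"`).
#' @param mu,sigma Gene expression mean and standard deviation.
#' @param seed Optional integer seed.
#' @return An `ExpressionDataset` with conditions set.
#' @export
simulate_null_dataset <- function(n_genes, n_a, n_b, mu = 6, sigma = 1,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- n_a + n_b
  vals <- matrix(stats::rnorm(n_genes * m, mu, sigma), n_genes, m)
  genes <- .gene_names("G", n_genes)
  samples <- sprintf(paste0("S%0", max(3L, nchar(m)), "d"), seq_len(m))
  dimnames(vals) <- list(genes, samples)
  suppressWarnings(expression_dataset(
    vals, stats::setNames(rep(c("A", "B"), c(n_a, n_b)), samples)))
}

#' Benchmark sweep over simulation scenarios
#'
#' Reproduces the benchmarking experiment design: for every combination of
#' case-to-total sample ratio, perturbed-gene fraction and perturbation type,
#' simulate `n_sims` independent benchmarks, run the differential pipeline
#' `n_runs` times on each (with distinct seeds), and score every run against
#' the ground truth with the Matthews correlation coefficient over the
#' network's candidate edges.
#'
#' @param case_ratios,perturb_fractions Numeric vectors of grid values in
#'   (0, 1).
#' @param perturbations Character vector of perturbation types.
#' @param n_sims Independent simulations per scenario (default 5).
#' @param n_runs Algorithm runs per simulation (default 5).
#' @param metric,rule,n_perm,alpha,s_form Pipeline settings passed to
#'   [run_dcnet()].
#' @param seed Integer seed controlling the whole sweep.
#' @param ... Further arguments to [simulate_benchmark()] (network size,
#'   noise, ...).
#' @return Tidy data frame with one row per run: `case_ratio`,
#'   `perturb_fraction`, `perturbation`, `sim`, `run`, `tp`, `fp`, `tn`,
#'   `fn`, `mcc`.
#' @export
benchmark_sweep <- function(case_ratios = 0.5, perturb_fractions = 0.1,
                            perturbations = c("knockdown", "diff_expr",
                                              "inversion", "loss_of_coexpr",
                                              "mixed"),
                            n_sims = 5, n_runs = 5,
                            metric = "pearson", rule = "either",
                            n_perm = 1000, alpha = 0.01,
                            s_form = "standard", seed = 42, ...) {
  stopifnot(all(case_ratios > 0 & case_ratios < 1),
            all(perturb_fractions > 0 & perturb_fractions < 1))
  set.seed(seed)
  grid <- expand.grid(case_ratio = case_ratios,
                      perturb_fraction = perturb_fractions,
                      perturbation = perturbations,
                      stringsAsFactors = FALSE)
  out <- vector("list", nrow(grid) * n_sims * n_runs)
  idx <- 0L
  for (g in seq_len(nrow(grid))) {
    for (si in seq_len(n_sims)) {
      sim_seed <- sample.int(.Machine$integer.max - 1L, 1L)
      bm <- simulate_benchmark(case_ratio = grid$case_ratio[g],
                               perturbation = grid$perturbation[g],
                               perturb_fraction = grid$perturb_fraction[g],
                               seed = sim_seed, ...)
      cand <- candidate_edges(bm$dataset, bm$network)
      for (ri in seq_len(n_runs)) {
        run_seed <- sample.int(.Machine$integer.max - 1L, 1L)
        res <- run_dcnet(bm$dataset, cand, metric = metric, n_perm = n_perm,
                         seed = run_seed, alpha = alpha, rule = rule,
                         s_form = s_form)
        cc <- edge_confusion(significant_edges(res), bm$truth_edges, cand)
        idx <- idx + 1L
        out[[idx]] <- data.frame(case_ratio = grid$case_ratio[g],
                                 perturb_fraction = grid$perturb_fraction[g],
                                 perturbation = grid$perturbation[g],
                                 sim = si, run = ri,
                                 tp = cc$tp, fp = cc$fp, tn = cc$tn,
                                 fn = cc$fn, mcc = mcc(cc),
                                 stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Write a simulated benchmark to a directory
#'
#' Writes `expr.tsv` (genes x samples), `cond.tsv`, `grn.tsv`,
#' `truth_edges.tsv` and `params.json` so a benchmark can be consumed by the
#' command-line interface or external tools.
#'
#' @param benchmark A `SimulatedBenchmark`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory path.
#' @export
write_benchmark <- function(benchmark, dir) {
  stopifnot(inherits(benchmark, "SimulatedBenchmark"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  vals <- benchmark$dataset$values
  expr <- data.frame(gene = rownames(vals), vals, check.names = FALSE,
                     stringsAsFactors = FALSE)
  utils::write.table(expr, file.path(dir, "expr.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cond <- data.frame(sample = colnames(vals),
                     condition = as.character(benchmark$dataset$conditions),
                     stringsAsFactors = FALSE)
  utils::write.table(cond, file.path(dir, "cond.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  grn <- data.frame(tf = benchmark$network$source,
                    tg = benchmark$network$target, stringsAsFactors = FALSE)
  utils::write.table(grn, file.path(dir, "grn.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(benchmark$truth_edges, file.path(dir, "truth_edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  params <- c(benchmark$params,
              list(perturbation = benchmark$perturbation,
                   perturbed_genes = benchmark$perturbed_genes))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(params, file.path(dir, "params.json"),
                         auto_unbox = TRUE, digits = NA)
  } else {
    dput(params, file.path(dir, "params.json"))
  }
  invisible(dir)
}
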