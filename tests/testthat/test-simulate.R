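test_that("the generated regulatory network is a TF-rooted tree", {
  for (sd_ in 1:5) {
    grn <- simulate_tree_grn(3, 7, seed = sd_)
    genes <- c(attr(grn, "tf"), attr(grn, "tg"))
    expect_length(genes, 10L)
    expect_identical(nrow(grn), 9L)  # n - 1 edges
    # every non-root node has in-degree exactly 1
    indeg <- table(factor(grn$target, levels = genes))
    expect_identical(sum(indeg == 0), 1L)          # the root
    expect_true(all(indeg <= 1))
    # regulators are always TFs; TGs never regulate
    expect_true(all(grn$source %in% attr(grn, "tf")))
    g <- igraph::graph_from_data_frame(grn, directed = FALSE)
    expect_true(igraph::is_connected(g))
    expect_false(igraph::any_loop(g))
  }
  one <- simulate_tree_grn(1, 1, seed = 1)
  expect_identical(nrow(one), 1L)
  expect_identical(one$source, attr(one, "tf"))
  expect_identical(one$target, attr(one, "tg"))
  expect_identical(simulate_tree_grn(5, 20, seed = 8),
                   simulate_tree_grn(5, 20, seed = 8))
})

test_that("the graph covariance decays as rho^distance and is positive definite", {
  grn <- simulate_tree_grn(3, 7, seed = 2)
  rho <- 0.8
  sig <- graph_covariance(grn, rho)
  expect_equal(unname(diag(sig)), rep(1, 10))
  d <- igraph::distances(igraph::graph_from_data_frame(grn, directed = FALSE))
  d <- d[rownames(sig), colnames(sig)]
  expect_equal(sig[d == 1], rep(rho, sum(d == 1)))
  expect_equal(sig[d == 2], rep(rho^2, sum(d == 2)))
  expect_gt(min(eigen(sig, symmetric = TRUE, only.values = TRUE)$values), 0)
  expect_error(graph_covariance(grn, 1.2), "rho")
  expect_error(graph_covariance(grn, 0), "rho")
})

test_that("simulated expression reproduces the model moments", {
  grn <- simulate_tree_grn(3, 7, seed = 3)
  m <- 4000
  ds <- simulate_expression(grn, m, rho = 0.8, mu = 6, sigma = 1, seed = 4)
  expect_identical(dim(ds$values), c(10L, as.integer(m)))
  expect_true(all(abs(rowMeans(ds$values) - 6) < 4 / sqrt(m)))
  e1 <- grn[1, ]
  r <- stats::cor(ds$values[e1$source, ], ds$values[e1$target, ])
  expect_lt(abs(r - 0.8), 0.05)
  expect_identical(simulate_expression(grn, 50, seed = 9)$values,
                   simulate_expression(grn, 50, seed = 9)$values)
})

test_that("mean perturbations shift the case group as configured", {
  for (sd_ in 1:5) {
    bm <- simulate_benchmark(n_tf = 4, n_tg = 16, m_samples = 60,
                             perturbation = "knockdown",
                             perturb_fraction = 0.2,
                             knockdown_factor = 0.1, seed = sd_)
    is_case <- bm$dataset$conditions == "case"
    for (g in bm$perturbed_genes) {
      expect_lt(mean(bm$dataset$values[g, is_case]),
                mean(bm$dataset$values[g, !is_case]))
    }
  }
  bm <- simulate_benchmark(n_tf = 4, n_tg = 16, m_samples = 400,
                           perturbation = "diff_expr", perturb_fraction = 0.2,
                           de_shift = 2, seed = 6)
  is_case <- bm$dataset$conditions == "case"
  g <- bm$perturbed_genes[1]
  expect_equal(mean(bm$dataset$values[g, is_case]) -
                 mean(bm$dataset$values[g, !is_case]), 2, tolerance = 0.5)
})

test_that("inversion flips and loss of co-expression removes case correlations", {
  bm <- simulate_benchmark(n_tf = 4, n_tg = 8, m_samples = 2000,
                           perturbation = "inversion", perturb_fraction = 0.2,
                           seed = 12)
  is_case <- bm$dataset$conditions == "case"
  te <- bm$truth_edges[1, ]
  r_ctrl <- stats::cor(bm$dataset$values[te$source, !is_case],
                       bm$dataset$values[te$target, !is_case])
  r_case <- stats::cor(bm$dataset$values[te$source, is_case],
                       bm$dataset$values[te$target, is_case])
  expect_gt(r_ctrl, 0.5)
  expect_lt(r_case, -0.5)

  bml <- simulate_benchmark(n_tf = 4, n_tg = 8, m_samples = 2000,
                            perturbation = "loss_of_coexpr",
                            perturb_fraction = 0.2, seed = 13)
  is_case <- bml$dataset$conditions == "case"
  tel <- bml$truth_edges[1, ]
  expect_lt(abs(stats::cor(bml$dataset$values[tel$source, is_case],
                           bml$dataset$values[tel$target, is_case])), 0.15)
})

test_that("the perturbed case model preserves untouched correlation entries", {
  grn <- simulate_tree_grn(5, 15, seed = 20)
  rho <- 0.8
  base <- graph_covariance(grn, rho)
  pert <- attr(grn, "tg")[1]  # a leaf: only its incident edge is affected
  for (type in c("inversion", "loss_of_coexpr")) {
    mod <- perturbed_model(grn, rho, stats::setNames(type, pert))
    others <- setdiff(rownames(base), pert)
    expect_true(all(abs(mod$corr[others, others] - base[others, others]) < 0.02))
  }
  # mean-only perturbations leave the correlation matrix exactly alone
  modk <- perturbed_model(grn, rho, stats::setNames("knockdown", pert))
  expect_equal(modk$corr, base, tolerance = 1e-12)
  expect_equal(unname(modk$mean[pert]), 0.6)
  modd <- perturbed_model(grn, rho, stats::setNames("diff_expr", pert),
                          de_shift = 2)
  expect_equal(unname(modd$mean[pert]), 8)
  expect_error(perturbed_model(grn, rho, stats::setNames("knockdown", pert),
                               knockdown_factor = 1.5), "knockdown_factor")
})

test_that("perturbed gene counts, TF priority and ground truth are consistent", {
  bm <- simulate_benchmark(n_tf = 20, n_tg = 80, m_samples = 30,
                           perturbation = "knockdown", perturb_fraction = 0.1,
                           seed = 15)
  expect_length(bm$perturbed_genes, 10L)  # round(0.1 * 100)
  # TFs are sampled first: a fraction below the TF count yields only TFs
  expect_true(all(bm$perturbed_genes %in% attr(bm$network, "tf")))
  expect_gt(nrow(bm$truth_edges), 0)
  # every truth edge touches a perturbed gene and lies in the network
  expect_true(all(bm$truth_edges$source %in% bm$perturbed_genes |
                    bm$truth_edges$target %in% bm$perturbed_genes))
  nk <- paste(bm$network$source, bm$network$target)
  expect_true(all(paste(bm$truth_edges$source, bm$truth_edges$target) %in% nk))
  # non-truth edges touch no perturbed gene
  non <- bm$network[!(nk %in% paste(bm$truth_edges$source, bm$truth_edges$target)), ]
  expect_false(any(non$source %in% bm$perturbed_genes |
                     non$target %in% bm$perturbed_genes))
})

test_that("benchmarks are fully deterministic per seed and support the null case", {
  b1 <- simulate_benchmark(n_tf = 3, n_tg = 9, m_samples = 30, seed = 77)
  b2 <- simulate_benchmark(n_tf = 3, n_tg = 9, m_samples = 30, seed = 77)
  expect_identical(b1$dataset$values, b2$dataset$values)
  expect_identical(b1$truth_edges, b2$truth_edges)
  expect_identical(b1$gene_types, b2$gene_types)

  b0 <- simulate_benchmark(n_tf = 3, n_tg = 9, m_samples = 30,
                           perturbation = "none", seed = 78)
  expect_length(b0$perturbed_genes, 0L)
  expect_identical(nrow(b0$truth_edges), 0L)

  expect_error(simulate_benchmark(m_samples = 30, case_ratio = 0.02, seed = 1),
               ">= 2 samples")
  expect_error(simulate_benchmark(perturb_fraction = 1.5, seed = 1),
               "perturb_fraction")
})

test_that("the sweep emits one scored row per scenario, simulation and run", {
  sw <- suppressWarnings(benchmark_sweep(
    case_ratios = c(0.4, 0.6), perturb_fractions = 0.2,
    perturbations = c("knockdown", "inversion"),
    n_sims = 2, n_runs = 2, n_perm = 200, seed = 5,
    n_tf = 3, n_tg = 9, m_samples = 30))
  expect_identical(nrow(sw), 2L * 2L * 2L * 2L)
  expect_named(sw, c("case_ratio", "perturb_fraction", "perturbation",
                     "sim", "run", "tp", "fp", "tn", "fn", "mcc"))
  expect_true(all(sw$tp + sw$fp + sw$tn + sw$fn == 11))  # 12 genes -> 11 edges
  expect_true(all(sw$mcc >= -1 & sw$mcc <= 1))
  one <- suppressWarnings(benchmark_sweep(
    case_ratios = 0.5, perturb_fractions = 0.2,
    perturbations = "knockdown", n_sims = 1, n_runs = 1,
    n_perm = 200, seed = 6, n_tf = 3, n_tg = 9, m_samples = 30))
  expect_identical(nrow(one), 1L)
})

test_that("a benchmark round-trips through its on-disk representation", {
  bm <- simulate_benchmark(n_tf = 3, n_tg = 9, m_samples = 24,
                           perturbation = "mixed", perturb_fraction = 0.25,
                           seed = 41)
  dir <- withr::local_tempdir()
  write_benchmark(bm, dir)
  ds <- read_expression(file.path(dir, "expr.tsv"))
  ds <- suppressWarnings(read_conditions(file.path(dir, "cond.tsv"), ds))
  expect_equal(ds$values, bm$dataset$values, tolerance = 1e-6)
  expect_identical(as.character(ds$conditions),
                   as.character(bm$dataset$conditions))
  cand <- candidate_edges(ds, utils::read.table(file.path(dir, "grn.tsv"),
                                                header = TRUE))
  expect_identical(nrow(cand), nrow(bm$network))
})
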