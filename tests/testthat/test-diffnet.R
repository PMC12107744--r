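test_that("the differential metrics reproduce their defining arithmetic", {
  expect_equal(delta_r(0.8, -0.3), 1.1)
  expect_equal(delta_r(0.4, 0.4), 0)
  expect_equal(delta_r(-1, 1), 2)
  expect_equal(shift_s(0.9, 0.9, 0.9), 0.9 - 2 * 1.8)
  expect_equal(shift_s(0, 0, 0), 0)
  expect_equal(shift_s(0.5, 0.5, -0.5), 0.5)
  expect_equal(shift_s(0.6, 0.4, 0.2, form = "centered"), 0.6 - 0.3)
  set.seed(33)
  ra <- runif(200, -1, 1); rb <- runif(200, -1, 1); rab <- runif(200, -1, 1)
  expect_identical(delta_r(ra, rb), abs(ra - rb))
  expect_identical(shift_s(rab, ra, rb), rab - 2 * (ra + rb))
  expect_true(all(delta_r(ra, rb) >= 0 & delta_r(ra, rb) <= 2))
})

test_that("BH adjustment matches the independent step-up oracle", {
  res <- adjust_pvalues(c(0.01, 0.02, 0.04, 0.05), alpha = 0.05)
  expect_equal(res$padj, c(0.04, 0.04, 0.05, 0.05))
  expect_identical(adjust_pvalues(rep(1, 5))$padj, rep(1, 5))
  expect_false(any(adjust_pvalues(rep(1, 5))$sig))
  one <- adjust_pvalues(0.005, alpha = 0.01)
  expect_equal(one$padj, 0.005)
  expect_true(one$sig)
  expect_error(adjust_pvalues(0.5, method = "magic"), "fdr_bh")
  expect_error(adjust_pvalues(c(0.5, 0)), "0, 1")

  set.seed(12)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    expect_equal(adjust_pvalues(p)$padj, bh_step_up(p), tolerance = 1e-14)
  }
  # adjusted never below raw
  p <- runif(100)
  expect_true(all(adjust_pvalues(p)$padj >= p))
})

test_that("a planted differential pair among decoys is recovered by delta_r", {
  # 50 decoys: the planted pair's delta_r clears the pooled null's far tail
  ds <- make_planted_dataset(50, 30, 30, r = 0.9, seed = 17)
  res <- run_dcnet(ds, n_perm = 1000, seed = 18, alpha = 0.01)
  e <- res$edges
  i <- which(e$source == "gx" & e$target == "gy")
  expect_length(i, 1L)
  expect_gt(e$delta_r[i], stats::quantile(res$background$null_delta_r, 0.99))
  expect_identical(e$p_delta_r[i], min(e$p_delta_r))

  # BH-significance needs p below alpha / E, i.e. N_p of order E / alpha:
  # with 20 decoys (231 pairs) and 40000 permutations the floor of the
  # adjusted p (231 / 40001) is well under alpha = 0.01
  ds2 <- make_planted_dataset(20, 30, 30, r = 0.9, seed = 19)
  res2 <- run_dcnet(ds2, n_perm = 40000, seed = 20, alpha = 0.01)
  e2 <- res2$edges
  j <- which(e2$source == "gx" & e2$target == "gy")
  expect_true(e2$sig_delta_r[j])
  sig <- significant_edges(res2, rule = "deltar")
  expect_true(any(sig$source == "gx" & sig$target == "gy"))
})

test_that("mode 2 output has exactly the candidate rows, directed", {
  ds <- make_planted_dataset(10, 15, 15, seed = 4)
  grn <- data.frame(tf = rep("gx", 10),
                    tg = c("gy", sprintf("d%02d", 1:9)))
  cand <- candidate_edges(ds, grn)
  res <- suppressWarnings(run_dcnet(ds, cand, n_perm = 500, seed = 5))
  expect_identical(nrow(res$edges), 10L)
  expect_identical(res$mode, 2L)
  expect_true(res$directed)
  expect_identical(res$edges$source, cand$source)
  expect_identical(res$edges$target, cand$target)
})

test_that("swapping the condition labels leaves both differential metrics unchanged", {
  ds <- make_planted_dataset(6, 12, 12, seed = 9)
  ds_sw <- ds
  lv <- levels(ds$conditions)
  sw <- stats::setNames(ifelse(ds$conditions == lv[1], lv[2], lv[1]),
                        names(ds$conditions))
  ds_sw <- suppressWarnings(set_conditions(ds_sw, sw))
  cand <- candidate_edges(ds)
  score <- function(d) {
    t(vapply(seq_len(nrow(cand)), function(i) {
      tr <- association_triple(d, c(cand$source[i], cand$target[i]))
      c(delta_r(tr$r_a, tr$r_b), shift_s(tr$r_ab, tr$r_a, tr$r_b))
    }, numeric(2)))
  }
  expect_equal(score(ds), score(ds_sw), tolerance = 1e-12)
})

test_that("swapping the genes of an undirected pair changes no score", {
  ds <- make_planted_dataset(3, 10, 10, seed = 14)
  for (mt in c("pearson", "spearman", "entropy")) {
    t1 <- association_triple(ds, c("gx", "gy"), metric = mt)
    t2 <- association_triple(ds, c("gy", "gx"), metric = mt)
    expect_equal(delta_r(t1$r_a, t1$r_b), delta_r(t2$r_a, t2$r_b),
                 tolerance = 1e-12)
    expect_equal(shift_s(t1$r_ab, t1$r_a, t1$r_b),
                 shift_s(t2$r_ab, t2$r_a, t2$r_b), tolerance = 1e-12)
  }
})

test_that("degenerate edges are reported with p = 1 and flagged, not dropped", {
  set.seed(2)
  vals <- rbind(rep(3, 20), matrix(rnorm(40), 2, 20))
  ds <- make_dataset(vals, 10, 10, genes = c("flat", "g1", "g2"))
  res <- suppressWarnings(run_dcnet(ds, n_perm = 500, seed = 3))
  e <- res$edges
  flat_rows <- e$source == "flat" | e$target == "flat"
  expect_identical(nrow(e), 3L)
  expect_true(all(e$degenerate[flat_rows]))
  expect_true(all(e$p_delta_r[flat_rows] == 1))
  expect_true(all(e$p_s[flat_rows] == 1))
  expect_false(any(e$sig_delta_r[flat_rows] | e$sig_s[flat_rows]))
})

test_that("the significance rules are the advertised boolean combinations", {
  ds <- make_planted_dataset(10, 15, 15, seed = 6)
  res <- suppressWarnings(run_dcnet(ds, n_perm = 500, seed = 7))
  e <- res$edges
  expect_identical(nrow(significant_edges(res, "either")),
                   sum(e$sig_delta_r | e$sig_s))
  expect_identical(nrow(significant_edges(res, "both")),
                   sum(e$sig_delta_r & e$sig_s))
  expect_identical(nrow(significant_edges(res, "deltar")), sum(e$sig_delta_r))
  expect_identical(nrow(significant_edges(res, "s")), sum(e$sig_s))
  expect_true(all(e$padj_delta_r >= e$p_delta_r))
  expect_true(all(e$padj_s >= e$p_s))
})
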