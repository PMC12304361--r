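test_that("log signal and variance reproduce hand-derived micro-examples", {
  expect_equal(peak_mean_log_signal(rbind(c(1, 1), c(1, 1))), 1)
  expect_equal(peak_mean_log_signal(rbind(c(0, 0), c(2, 2))), 1)
  expect_true(is.na(peak_mean_log_signal(matrix(0, 2, 2))))
  expect_error(peak_mean_log_signal(matrix(0, 0, 0)), "empty")

  expect_equal(peak_log_variance(rbind(c(1, 1), c(1, 1))), 0)
  # quad-sum 8, total 4, n_b 2 -> 8 / (ln2 * 2 * 4) = 1/ln2
  expect_equal(peak_log_variance(rbind(c(0, 0), c(2, 2))), 1 / log(2),
               tolerance = 1e-12)
  expect_error(peak_log_variance(matrix(0, 2, 2)), "positive")
})

test_that("fast variance equals the literal covariance quadruple sum", {
  set.seed(101)
  for (k in 1:60) {
    c <- random_count_block(sample(2:12, 1), sample(2:20, 1),
                            lambda = runif(1, 0.5, 4))
    if (sum(c) == 0) next
    expect_equal(peak_log_variance(c), naive_sigma2(c), tolerance = 1e-10)
  }
  # sparse input takes the same path
  m <- Matrix::Matrix(random_count_block(6, 8), sparse = TRUE)
  expect_equal(peak_log_variance(m), naive_sigma2(as.matrix(m)),
               tolerance = 1e-12)
})

test_that("variance is zero exactly when all cell row sums are equal", {
  expect_equal(peak_log_variance(rbind(c(2, 0), c(0, 2))), 0)
  expect_gt(peak_log_variance(rbind(c(2, 0), c(0, 1))), 0)
  set.seed(7)
  for (k in 1:20) {
    c <- random_count_block(5, 4)
    if (sum(c) == 0) next
    expect_gte(peak_log_variance(c), 0)
  }
})

test_that("delta-mode variance matches the first-order form", {
  set.seed(8)
  c <- random_count_block(10, 6)
  r <- rowSums(c)
  expected <- length(r) * var(r) / (log(2)^2 * sum(c)^2)
  expect_equal(peak_log_variance(c, mode = "delta"), expected,
               tolerance = 1e-12)
})

test_that("z-score composes the summaries with the A-minus-B convention", {
  a <- peak_condition_summary(rbind(c(0, 0), c(2, 2)))
  b <- peak_condition_summary(rbind(c(2, 2), c(2, 2)))
  expect_equal(a$zbar, 1); expect_equal(b$zbar, 2)
  z <- peak_zscore(a, b)
  expect_equal(z$z, -1 / sqrt(1 / log(2)), tolerance = 1e-9)
  expect_equal(z$z, -0.83255, tolerance = 1e-4)
  # antisymmetry and self-comparison
  expect_equal(peak_zscore(b, a)$z, -z$z)
  expect_equal(peak_zscore(a, a)$z, 0)
  # status propagation
  zt <- peak_condition_summary(matrix(0, 2, 2))
  expect_equal(peak_zscore(zt, b)$status, "zero_total_a")
  expect_equal(peak_zscore(b, zt)$status, "zero_total_b")
  c1 <- peak_condition_summary(rbind(c(1, 1), c(1, 1)))
  c2 <- peak_condition_summary(rbind(c(2, 2), c(2, 2)))
  zz <- peak_zscore(c1, c2)
  expect_equal(zz$status, "zero_variance")
  expect_true(is.na(zz$z))
  expect_equal(peak_zscore(c2, c2), list(z = 0, status = "zero_variance"))
})

test_that("normal p-values are two-sided and symmetric", {
  expect_equal(zscore_pvalues(0), 1)
  expect_equal(zscore_pvalues(1.959964), 0.05, tolerance = 1e-6)
  expect_equal(zscore_pvalues(-1.959964), zscore_pvalues(1.959964))
  z <- rnorm(50)
  expect_true(all(zscore_pvalues(z) > 0 & zscore_pvalues(z) <= 1))
})

test_that("BH adjustment matches the hand-computed step-up and is stable", {
  expect_equal(bh_adjust(c(0.01, 0.03, 0.04)), c(0.03, 0.04, 0.04))
  expect_equal(bh_adjust(1), 1)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  set.seed(9)
  p <- runif(40)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  # permutation invariance
  perm <- sample(40)
  expect_equal(bh_adjust(p[perm]), adj[perm])
})

test_that("run_differential composes the verified parts per peak", {
  a <- toy_binned_counts(rbind(c(0, 0), c(2, 2)), "A")
  b <- toy_binned_counts(rbind(c(2, 2), c(2, 2)), "B")
  res <- tidy(run_differential(a, b))
  expect_equal(nrow(res), 1)
  expect_equal(res$z, -0.83255, tolerance = 1e-4)
  expect_equal(res$zbar_a, 1); expect_equal(res$zbar_b, 2)
  expect_equal(res$var_a, 1 / log(2), tolerance = 1e-12)
  # A vs A: z = 0 (or zero-variance status), p = 1, nothing selected
  same <- tidy(run_differential(a, a))
  expect_true(all(same$z[same$status == "ok"] == 0))
  expect_false(any(same$selected))
  g <- glance(run_differential(a, b))
  expect_equal(g$n_peaks, 1)
  expect_equal(g$n_tested, 1)
})

test_that("run_differential agrees with per-peak summaries on simulated data", {
  sim <- tiny_sim()
  w <- make_windows(sim$peaks)
  bm <- build_matrix(dplyr::bind_rows(sim$fragments), w, sim$design)
  a <- normalize_total(bm$matrices$A); b <- normalize_total(bm$matrices$B)
  res <- tidy(run_differential(a, b))
  nb <- a$n_bins
  for (p in sample(seq_along(a$peak_ids), 5)) {
    cols <- ((p - 1) * nb + 1):(p * nb)
    sa <- peak_condition_summary(a$counts[, cols, drop = FALSE])
    sb <- peak_condition_summary(b$counts[, cols, drop = FALSE])
    expect_equal(res$zbar_a[p], sa$zbar, tolerance = 1e-10)
    expect_equal(res$var_b[p], sb$var, tolerance = 1e-10)
    expect_equal(res$z[p], peak_zscore(sa, sb)$z, tolerance = 1e-10)
  }
  # antisymmetry of the whole table
  rev <- tidy(run_differential(b, a))
  ok <- res$status == "ok"
  expect_equal(rev$z[ok], -res$z[ok], tolerance = 1e-12)
})

test_that("zero-total peaks carry status and are excluded from the BH family", {
  blockA <- cbind(matrix(1, 2, 2), matrix(0, 2, 2))
  blockB <- cbind(matrix(2, 2, 2), matrix(0, 2, 2))
  a <- new_binned_counts(blockA, c("a1", "a2"), c("p1", "p2"), 2L, "A")
  b <- new_binned_counts(blockB, c("b1", "b2"), c("p1", "p2"), 2L, "B")
  res <- tidy(run_differential(a, b))
  expect_equal(res$status, c("zero_variance", "zero_total_a"))
  expect_true(all(is.na(res$padj[res$status != "ok"])))
  expect_false(any(res$selected))
})

test_that("mismatched matrices and wrong pipeline stages are rejected", {
  a <- toy_binned_counts(rbind(c(0, 0), c(2, 2)), "A")
  b3 <- toy_binned_counts(rbind(c(1, 1, 1), c(1, 1, 1)), "B")
  expect_error(run_differential(a, b3), "different")
  b <- toy_binned_counts(rbind(c(2, 2), c(2, 2)), "B")
  expect_error(suppressWarnings(run_differential(normalize_total(a), b)), "scaled")
  expect_error(
    run_differential(log1p_transform(a), log1p_transform(b)),
    "log1p")
})
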