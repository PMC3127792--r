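# Genome scan, permutation threshold, and the power-study plumbing.
# Small designs keep these cheap; the reference-scale runs live in the
# acceptance suite.

scan_ctl <- function() {
  sm_control(n_starts = 1, nm_maxit = 0, bfgs_maxit = 30, bfgs_reltol = 1e-8,
             cycles = 1, inner_maxit = 25, inner_tol = 1e-6)
}

test_that("scan grid covers every interval at the configured step", {
  map <- toy_map(spacing = 10, n_mark = 3)
  g <- scan_grid(map, step = 2.5)
  expect_equal(g$pos_cm, seq(0, 20, by = 2.5))
  g2 <- scan_grid(map, step = 3)  # marker positions always included
  expect_true(all(map$pos_cm %in% g2$pos_cm))
})

test_that("a scan finds a strong marker-coincident QTL and LR >= 0", {
  map <- toy_map(spacing = 10, n_mark = 4)
  sim <- simulate_dataset(n = 60, map = map, qtl_pos_cm = 10, h2 = 0.2,
                          seed = 41)
  sc <- genome_scan(sim$pheno, sim$geno, map, step = 10,
                    control = scan_ctl())
  expect_s3_class(sc, "sm_scan")
  expect_equal(nrow(sc), 4)
  expect_true(all(sc$lr >= 0, na.rm = TRUE))
  expect_equal(sc$pos_cm[which.max(sc$lr)], 10, tolerance = 5)
  # the scan LR at a marker equals a standalone fit at that marker
  pos <- qtl_position(map, "LG1", 10)
  om <- qtl_genotype_probs(sim$geno, map, pos)
  m0 <- attr(sc, "m0")
  m1 <- fit_m1(sim$pheno, om, scan_ctl(),
               theta_start = NULL,
               extra_starts = list(cbind(m0$theta, m0$theta)))
  standalone <- lr_statistic(m1, m0)
  expect_equal(sc$lr[sc$pos_cm == 10], standalone,
               tolerance = 0.02 * (1 + standalone))
})

test_that("a null dataset yields a flat low profile", {
  map <- toy_map(spacing = 10, n_mark = 3)
  p1 <- default_qtl_params()[[1]]
  sim <- simulate_dataset(n = 50, map = map, params_pair = list(p1, p1),
                          h2 = NULL, sigma = c(0.5, 0.3, 0.2), seed = 43)
  sc <- genome_scan(sim$pheno, sim$geno, map, step = 10,
                    control = scan_ctl())
  expect_true(all(sc$lr < 30, na.rm = TRUE))
})

test_that("permutation thresholds are reproducible and quantile-monotone", {
  map <- toy_map(spacing = 15, n_mark = 2)
  sim <- simulate_dataset(n = 40, map = map, h2 = 0.1, seed = 47)
  pt1 <- permutation_threshold(sim$pheno, sim$geno, map, n_perm = 25,
                               quantile = 0.8, seed = 5, step = 15,
                               control = scan_ctl())
  pt2 <- permutation_threshold(sim$pheno, sim$geno, map, n_perm = 25,
                               quantile = 0.8, seed = 5, step = 15,
                               control = scan_ctl())
  expect_identical(pt1$maxima, pt2$maxima)
  expect_equal(pt1$threshold, pt2$threshold)
  # quantile 0 is the minimum of the maxima; higher quantiles not below
  q0 <- stats::quantile(pt1$maxima, 0)
  expect_equal(as.numeric(q0), min(pt1$maxima))
  expect_gte(as.numeric(stats::quantile(pt1$maxima, 0.9)),
             as.numeric(stats::quantile(pt1$maxima, 0.5)))
  expect_error(permutation_threshold(sim$pheno, sim$geno, map, n_perm = 10,
                                     quantile = 0.95, seed = 1),
               "too small")
})

test_that("power study returns calibrated proportions on a toy design", {
  res <- power_study(h2_grid = 0.3, n_replicates = 20, n = 40,
                     map = toy_map(spacing = 20, n_mark = 2),
                     times = c(2, 2.2, 2.5, 3, 4.5, 7),
                     n_perm = 25, quantile = 0.8, step = 20,
                     control = scan_ctl(), seed = 17)
  expect_s3_class(res, "sm_power")
  expect_true(res$power >= 0 && res$power <= 1)
  expect_true(res$fpr >= 0 && res$fpr <= 1)
  # h2 = 0.3 on n = 40 with a marker-coincident QTL is an easy detection
  expect_gte(res$power, 0.6)
  det <- attr(res, "details")
  expect_equal(nrow(det), 20)
})

test_that("interval positions fit and yield a finite non-negative LR", {
  map <- toy_map(spacing = 20, n_mark = 2)
  sim <- simulate_dataset(n = 30, map = map, qtl_pos_cm = 0, h2 = 0.2,
                          seed = 53)
  sc <- genome_scan(sim$pheno, sim$geno, map, step = 10,
                    control = scan_ctl())
  expect_equal(sc$pos_cm, c(0, 10, 20))
  expect_true(all(is.finite(sc$lr)))
  expect_true(all(sc$lr >= 0))
})

test_that("autoplot produces a ggplot for scans and trajectories", {
  map <- toy_map(spacing = 10, n_mark = 3)
  sc <- structure(tibble::tibble(group = "LG1", pos_cm = c(0, 5, 10),
                                 lr = c(1, 5, 2)),
                  class = c("sm_scan", class(tibble::tibble())))
  expect_s3_class(autoplot(sc, threshold = 3), "ggplot")
  tr <- solve_trajectory(default_qtl_params()[[1]], c(2, 3, 4, 5))
  expect_s3_class(autoplot(tr), "ggplot")
})
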