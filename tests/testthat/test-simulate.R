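# Synthetic-data generator: the package's reference study conditions.

test_that("the default map matches the reference design dimensions", {
  map <- sim_map()
  expect_equal(length(unique(map$group)), 25)
  expect_equal(nrow(map), 950)
  expect_true(all(table(map$group) == 38))
})

test_that("zero map distance gives identical genotype columns", {
  map <- linkage_map(data.frame(group = 1, marker = c("a", "b", "c"),
                                pos_cm = c(0, 1e-9, 10)))
  g <- simulate_ril_genomes(map, 50, seed = 1)
  expect_equal(g[, "a"], g[, "b"])
})

test_that("adjacent-marker recombinants match the RIL expansion", {
  map <- linkage_map(data.frame(group = 1, marker = c("a", "b"),
                                pos_cm = c(0, 10)))
  g <- simulate_ril_genomes(map, 2000, seed = 99)
  rec <- mean(g[, 1] != g[, 2])
  R <- ril_expansion(haldane_cm_to_r(10))  # 0.1543
  expect_equal(R, 2 * haldane_cm_to_r(10) / (1 + 2 * haldane_cm_to_r(10)))
  # binomial 99.9% interval around R at n = 2000
  expect_lt(abs(rec - R), 3.3 * sqrt(R * (1 - R) / 2000))
})

test_that("markers segregate 1:1 and unlinked groups are uncorrelated", {
  map <- sim_map(n_groups = 4, n_markers = 40, length_cm = 80)
  g <- simulate_ril_genomes(map, 500, seed = 7)
  counts <- colSums(g == "A")
  pvals <- vapply(counts, function(x) {
    stats::binom.test(x, 500)$p.value
  }, numeric(1))
  expect_gte(mean(pvals > 0.01), 0.95)
  x1 <- as.numeric(g[, 1] == "A")          # group 1, first marker
  x2 <- as.numeric(g[, 11] == "A")         # group 2, first marker
  expect_lt(abs(cor(x1, x2)), 0.1)
})

test_that("heritability-to-sigma follows the variance decomposition", {
  # h2 = 0.5 with a mean difference of 2 gives sigma_g^2 = sigma^2 = 1
  p1 <- ode_params(1, 0, 0, 1, 0, 1, 0, 0, init_L = 1, init_S = 1, init_R = 1)
  p2 <- ode_params(1, 0, 0, 1, 0, 1, 0, 0, init_L = 3, init_S = 3, init_R = 3)
  s2 <- heritability_to_sigma(list(p1, p2), c(0, 1, 2, 3), h2 = 0.5,
                              t_star = 0)
  expect_equal(as.numeric(s2), rep(1, 3), tolerance = 1e-8)
  expect_equal(unname(attr(s2, "sigma_g2")), rep(1, 3), tolerance = 1e-8)
  # h2 -> 1 drives the noise to zero
  s2b <- heritability_to_sigma(list(p1, p2), c(0, 1, 2, 3), h2 = 0.999,
                               t_star = 0)
  expect_lt(max(s2b), 2e-3)
  expect_error(heritability_to_sigma(list(p1, p1), c(0, 1, 2, 3), 0.5),
               "undefined")
  expect_error(heritability_to_sigma(list(p1, p2), c(0, 1, 2, 3), 1.2),
               "0, 1")
})

test_that("reference-condition sigmas match an independent recomputation", {
  pp <- default_qtl_params()
  times <- c(2, 2.2, 2.5, 3, 4.5, 7)
  s2 <- heritability_to_sigma(pp, times, 0.05)
  # spreadsheet-style oracle: solve the two ODE means independently with a
  # fine-grid Euler integration and apply the variance decomposition
  euler <- function(p, t_end) {
    h <- 1e-4
    y <- c(p$init_L, p$init_S, p$init_R)
    t <- 2
    while (t < t_end - h / 2) {
      W <- sum(y)
      y <- y + h * c(p$alpha_L * W^p$beta_L - p$gamma_L * y[1],
                     p$alpha_S * W^p$beta_S,
                     p$alpha_R * W^p$beta_R - p$gamma_R * y[3])
      t <- t + h
    }
    y
  }
  t_star <- times[3]
  m1 <- euler(pp[[1]], t_star)
  m2 <- euler(pp[[2]], t_star)
  oracle <- ((m1 - m2)^2 / 4) * (1 - 0.05) / 0.05
  expect_equal(as.numeric(s2), oracle, tolerance = 1e-3)
})

test_that("phenotype simulation is deterministic and honours sigma = 0", {
  map <- toy_map()
  a <- simulate_dataset(n = 30, map = map, seed = 5)
  b <- simulate_dataset(n = 30, map = map, seed = 5)
  expect_identical(a$pheno, b$pheno)
  expect_identical(a$geno, b$geno)
  d <- simulate_dataset(n = 30, map = map, seed = 6)
  expect_false(identical(a$pheno, d$pheno))
  # zero noise: phenotypes equal the genotype mean curves exactly
  z <- simulate_dataset(n = 10, map = map, sigma = c(0, 0, 0), h2 = NULL,
                        seed = 7)
  mu <- lapply(z$truth$params_pair, solve_trajectory,
               times = z$truth$times)
  for (i in 1:10) {
    g <- z$truth$genotype[i]
    yi <- z$pheno[z$pheno$ril == rownames(z$geno)[i], ]
    expect_equal(yi$leaf, mu[[g]]$M_L, tolerance = 1e-10)
    expect_equal(yi$root, mu[[g]]$M_R, tolerance = 1e-10)
  }
})

test_that("QTL genotypes follow the marker at a marker-coincident QTL", {
  map <- toy_map()
  sim <- simulate_dataset(n = 40, map = map, qtl_pos_cm = 20, seed = 9)
  mk <- sim$geno[, which(map$pos_cm == 20)]
  expect_equal(sim$truth$genotype, unname(ifelse(mk == "A", 1L, 2L)))
})

test_that("empirical mid-season heritability approaches the target", {
  map <- toy_map(n_mark = 2)
  sim <- simulate_dataset(n = 5000, map = map, qtl_pos_cm = 0, h2 = 0.05,
                          seed = 21)
  t_star <- sim$truth$times[3]
  mu <- lapply(sim$truth$params_pair, solve_trajectory,
               times = sim$truth$times)
  i_star <- which(sim$truth$times == t_star)
  for (k in 1:3) {
    tr <- c("leaf", "stem", "root")[k]
    yk <- sim$pheno[[tr]][sim$pheno$time == t_star]
    gv <- vapply(sim$truth$genotype, function(g) {
      c(mu[[g]]$M_L[i_star], mu[[g]]$M_S[i_star], mu[[g]]$M_R[i_star])[k]
    }, numeric(1))
    h2_hat <- stats::var(gv) / stats::var(yk)
    expect_lt(abs(h2_hat - 0.05), 0.01)
  }
})

test_that("time jitter and drop-out produce ragged data the fits accept", {
  map <- toy_map(n_mark = 2)
  sim <- simulate_dataset(n = 12, map = map, qtl_pos_cm = 0,
                          time_jitter = 0.08, dropout = 0.15, seed = 31)
  tms <- split(sim$pheno$time, sim$pheno$ril)
  expect_gt(length(unique(unlist(tms))), 6)       # per-RIL grids differ
  expect_true(any(lengths(tms) < 6))              # some records dropped
  expect_true(all(vapply(tms, function(t) all(diff(t) > 0), TRUE)))
  # the ragged collection goes straight through the single-curve fit
  fit <- fit_m0(sim$pheno, sm_control(n_starts = 1, nm_maxit = 0,
                                      bfgs_maxit = 20, cycles = 1))
  expect_true(is.finite(fit$loglik))
  expect_error(simulate_dataset(n = 5, map = map, time_jitter = 0.2,
                                seed = 1), "half the smallest")
})
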