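# Mixture likelihood and the parameter-cascading outer fits.

test_that("mixture log-likelihood matches a brute-force oracle", {
  # 3 RILs, 2 times, hand-set weights and curves
  times <- c(1, 2)
  y <- tibble::tibble(
    ril = rep(c("a", "b", "c"), each = 2), time = rep(times, 3),
    leaf = c(1.0, 1.5, 0.8, 1.9, 1.2, 1.4),
    stem = c(2.0, 2.5, 2.2, 2.4, 1.8, 2.9),
    root = c(0.5, 0.9, 0.4, 1.0, 0.6, 0.8))
  omega <- rbind(c(0.9, 0.1), c(0.3, 0.7), c(0.5, 0.5))
  rownames(omega) <- c("a", "b", "c")
  mu <- tibble::tibble(
    genotype = rep(1:2, each = 2), time = rep(times, 2),
    leaf = c(1.1, 1.6, 0.9, 1.8), stem = c(2.1, 2.6, 2.0, 2.5),
    root = c(0.55, 0.85, 0.45, 0.95))
  psi <- noise_model(c(0.04, 0.09, 0.01))
  got <- mixture_loglik(y, omega, mu, psi)
  # brute force: explicit product of univariate normal densities
  oracle <- 0
  for (i in 1:3) {
    ri <- c("a", "b", "c")[i]
    li <- 0
    for (j in 1:2) {
      dens <- 1
      for (k in 1:3) {
        tr <- c("leaf", "stem", "root")[k]
        for (t in 1:2) {
          yv <- y[[tr]][y$ril == ri][t]
          mv <- mu[[tr]][mu$genotype == j][t]
          dens <- dens * stats::dnorm(yv, mv, sqrt(psi$sigma2[k]))
        }
      }
      li <- li + omega[i, j] * dens
    }
    oracle <- oracle + log(li)
  }
  expect_equal(as.numeric(got), as.numeric(oracle), tolerance = 1e-12)
})

test_that("degenerate and collapsed mixtures reduce correctly", {
  fx <- ode_pheno(n_per = 3, sigma = 0.1, seed = 2)
  mu1 <- fitted_curves(inner_fit(fx$pheno, fx$omega, default_qtl_params(),
                                 lambda = 10))
  psi <- noise_model(c(0.01, 0.01, 0.01))
  # omega = (1, 0): plain MVN log-likelihood of genotype-1 curves
  om10 <- matrix(rep(c(1, 0), each = 6), 6)
  rownames(om10) <- unique(fx$pheno$ril)
  l1 <- mixture_loglik(fx$pheno, om10, mu1, psi)
  mu_only1 <- mu1[mu1$genotype == 1, ]
  direct <- 0
  for (ri in unique(fx$pheno$ril)) {
    yi <- fx$pheno[fx$pheno$ril == ri, ]
    idx <- match(yi$time, mu_only1$time)
    for (k in 1:3) {
      tr <- c("leaf", "stem", "root")[k]
      direct <- direct + sum(stats::dnorm(yi[[tr]], mu_only1[[tr]][idx],
                                          sqrt(psi$sigma2[k]), log = TRUE))
    }
  }
  expect_equal(as.numeric(l1), direct, tolerance = 1e-10)
  # identical component curves: likelihood independent of omega
  mu_same <- mu1
  mu_same[mu_same$genotype == 2, c("leaf", "stem", "root")] <-
    mu_only1[c("leaf", "stem", "root")]
  set.seed(1)
  for (trial in 1:3) {
    w <- runif(6)
    om <- cbind(w, 1 - w)
    rownames(om) <- unique(fx$pheno$ril)
    l_any <- mixture_loglik(fx$pheno, om, mu_same, psi)
    l_half <- mixture_loglik(fx$pheno, matrix(0.5, 6, 2,
                                              dimnames = list(unique(fx$pheno$ril), NULL)),
                             mu_same, psi)
    expect_equal(as.numeric(l_any), as.numeric(l_half), tolerance = 1e-10)
  }
})

test_that("mixture likelihood is invariant under genotype relabelling", {
  fx <- ode_pheno(n_per = 4, sigma = 0.3, seed = 9)
  mu <- fitted_curves(inner_fit(fx$pheno, fx$omega, default_qtl_params(),
                                lambda = 100))
  psi <- noise_model(c(0.1, 0.2, 0.05))
  l <- mixture_loglik(fx$pheno, fx$omega, mu, psi)
  mu_sw <- mu
  mu_sw$genotype <- 3 - mu$genotype
  mu_sw <- mu_sw[order(mu_sw$genotype, mu_sw$time), ]
  l_sw <- mixture_loglik(fx$pheno, fx$omega[, 2:1], mu_sw, psi)
  expect_equal(as.numeric(l), as.numeric(l_sw), tolerance = 1e-10)
})

test_that("noiseless data are recovered within 1 percent", {
  fx <- ode_pheno(n_per = 10, sigma = 1e-4, seed = 4)
  truth <- sapply(default_qtl_params(), function(p) unlist(p)[1:8])
  fit <- fit_m1(fx$pheno, fx$omega,
                sm_control(n_starts = 1, nm_maxit = 0, bfgs_maxit = 300,
                           cycles = 2, fix_sigma = c(1, 1, 1) * 1e-2),
                theta_start = truth * exp(0.05))
  expect_lt(max(abs(fit$theta - truth) / truth), 0.01)
})

test_that("single-genotype noiseless fit recovers its parameters", {
  fx <- ode_pheno(n_per = 8, sigma = 1e-4, seed = 6)
  keep <- sprintf("R%03d", 1:8)
  y1 <- fx$pheno[fx$pheno$ril %in% keep, ]
  truth <- unlist(default_qtl_params()[[1]])[1:8]
  fit <- fit_m0(y1, sm_control(n_starts = 1, nm_maxit = 0, bfgs_maxit = 300,
                               cycles = 2, fix_sigma = c(1, 1, 1) * 1e-2),
                theta_start = matrix(truth * exp(-0.05), 8))
  expect_lt(max(abs(fit$theta[, 1] - truth) / truth), 0.01)
})

test_that("M1 nests M0 and the LR statistic behaves", {
  set.seed(31)
  fx <- ode_pheno(n_per = 8, sigma = 0.3, seed = 31)
  ctl <- sm_control(n_starts = 2, nm_maxit = 0, bfgs_maxit = 80, cycles = 1)
  m0 <- fit_m0(fx$pheno, ctl)
  m1 <- fit_m1(fx$pheno, fx$omega, ctl,
               extra_starts = list(cbind(m0$theta, m0$theta)))
  expect_gte(m1$loglik, m0$loglik - 1e-4)
  lr <- lr_statistic(m1, m0)
  expect_gte(lr, 0)
  expect_equal(lr, 2 * (m1$loglik - m0$loglik), tolerance = 1e-8)
  expect_equal(lr_statistic(m1, m1), 0)
  # mismatched data are refused
  other <- ode_pheno(n_per = 8, sigma = 0.3, seed = 32)
  m0b <- fit_m0(other$pheno, ctl)
  expect_error(lr_statistic(m1, m0b), "same data")
})

test_that("parameter cascading agrees with a direct ODE-solve fit", {
  # independent route: solve the ODE numerically per genotype and maximize
  # the same likelihood by a generic optimizer (no splines anywhere)
  fx <- ode_pheno(n_per = 6, sigma = 1e-3, seed = 8)
  truth <- sapply(default_qtl_params(), function(p) unlist(p)[1:8])
  sig2 <- c(1, 1, 1) * 1e-2
  # strong penalty on a transient-resolving basis, so the cascade
  # approximates the exact-likelihood route it is compared with
  ctl <- sm_control(lambda = 1e3, max_span = 0.15, n_starts = 1,
                    nm_maxit = 0, bfgs_maxit = 400, cycles = 3,
                    fix_sigma = sig2)
  casc <- fit_m1(fx$pheno, fx$omega, ctl, theta_start = truth * exp(0.03))
  times <- sort(unique(fx$pheno$time))
  inits <- lapply(default_qtl_params(), function(p) {
    c(p$init_L, p$init_S, p$init_R)
  })
  pos <- c(1, 3, 4, 6, 8)   # alphas and gammas, log-transformed
  # free auxiliary initial states, like the spline representation does
  direct_obj <- function(v) {
    if (any(!is.finite(v)) || any(abs(v) > 30)) return(1e10)
    th <- matrix(v[1:16], 8, 2)
    th[pos, ] <- exp(th[pos, ])
    in2 <- matrix(exp(v[17:22]), 3, 2)
    ll <- 0
    for (j in 1:2) {
      pj <- as_ode_params(c(as.list(stats::setNames(th[, j],
        c("alpha_L", "beta_L", "gamma_L", "alpha_S", "beta_S",
          "alpha_R", "beta_R", "gamma_R"))),
        list(init_L = in2[1, j], init_S = in2[2, j], init_R = in2[3, j])))
      tr <- try(solve_trajectory(pj, times), silent = TRUE)
      if (inherits(tr, "try-error")) return(1e10)
      sel <- fx$genotype == j
      for (i in which(sel)) {
        yi <- fx$pheno[fx$pheno$ril == sprintf("R%03d", i), ]
        ll <- ll + sum(stats::dnorm(yi$leaf, tr$M_L, sqrt(sig2[1]), log = TRUE)) +
          sum(stats::dnorm(yi$stem, tr$M_S, sqrt(sig2[2]), log = TRUE)) +
          sum(stats::dnorm(yi$root, tr$M_R, sqrt(sig2[3]), log = TRUE))
      }
    }
    -ll
  }
  v0 <- truth * exp(0.03)
  v0[pos, ] <- log(v0[pos, ])
  v0 <- c(as.numeric(v0), log(unlist(inits)))
  op <- stats::optim(v0, direct_obj, method = "BFGS",
                     control = list(maxit = 300, reltol = 1e-13,
                                    ndeps = rep(1e-5, 22)))
  op <- stats::optim(op$par, direct_obj, method = "BFGS",
                     control = list(maxit = 300, reltol = 1e-13,
                                    ndeps = rep(1e-5, 22)))
  th_direct <- matrix(op$par[1:16], 8, 2)
  th_direct[pos, ] <- exp(th_direct[pos, ])
  expect_lt(max(abs(casc$theta - th_direct) / abs(th_direct)), 0.02)
})

test_that("estimates are labelled by marker phase, not likelihood order", {
  fx <- ode_pheno(n_per = 6, sigma = 0.05, seed = 12)
  ctl <- sm_control(n_starts = 1, nm_maxit = 0, bfgs_maxit = 150, cycles = 1)
  fit <- fit_m1(fx$pheno, fx$omega, ctl)
  truth <- sapply(default_qtl_params(), function(p) unlist(p)[1:8])
  # genotype 1 column must match genotype-1 truth, not genotype 2's
  d_same <- max(abs(fit$theta[1, ] - truth[1, ]))
  d_swap <- max(abs(fit$theta[1, ] - truth[1, 2:1]))
  expect_lt(d_same, d_swap)
})

test_that("tidy and glance summarise fits in broom shape", {
  fx <- ode_pheno(n_per = 3, sigma = 0.2, seed = 13)
  ctl <- sm_control(n_starts = 1, nm_maxit = 0, bfgs_maxit = 30, cycles = 1)
  fit <- fit_m1(fx$pheno, fx$omega, ctl)
  td <- tidy(fit)
  expect_equal(nrow(td), 16)
  expect_named(td, c("model", "genotype", "term", "estimate"))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n, 6)
  expect_equal(gl$model, "M1")
})
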