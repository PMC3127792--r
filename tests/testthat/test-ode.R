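test_that("the RHS matches a hand-coded arithmetic oracle", {
  # reference genotype parameter set (first biomass QTL, parent-1 class)
  p <- ode_params(alpha_L = 2.09, beta_L = 0.16, gamma_L = 0.43,
                  alpha_S = 0.93, beta_S = 0.07,
                  alpha_R = 1.52, beta_R = 0.66, gamma_R = 2.91)
  s <- c(1, 1, 1)
  W <- 3
  oracle <- c(2.09 * W^0.16 - 0.43 * 1,
              0.93 * W^0.07,
              1.52 * W^0.66 - 2.91 * 1)
  expect_equal(unname(ode_rhs(s, p)), oracle, tolerance = 1e-12)
})

test_that("dW/dt equals the sum of organ derivatives and simple limits hold", {
  p <- ode_params(1.2, 0, 0, 0.7, 0, 0.4, 0, 0)
  d <- ode_rhs(c(2, 3, 4), p)
  expect_equal(unname(d), c(1.2, 0.7, 0.4))   # beta = gamma = 0: constants
  # leaf fixed point: M_L = (alpha_L / gamma_L) W^beta_L
  p2 <- ode_params(2, 0.3, 0.5, 1, 0.1, 1, 0.4, 1)
  st <- c(4, 1, 1)
  st[1] <- (2 / 0.5) * sum(st[1] + 1 + 1)^0.3  # solve self-consistently
  for (i in 1:50) st[1] <- (2 / 0.5) * (st[1] + 2)^0.3
  expect_equal(unname(ode_rhs(st, p2))[1], 0, tolerance = 1e-8)
  expect_error(ode_rhs(c(-1, 1, 1), p), "positive")
})

test_that("solver reproduces the linear closed form when beta = gamma = 0", {
  p <- ode_params(1.5, 0, 0, 0.8, 0, 0.3, 0, 0,
                  init_L = 1, init_S = 2, init_R = 3)
  tt <- seq(2, 7, by = 0.5)
  tr <- solve_trajectory(p, tt)
  expect_equal(tr$M_L, 1 + 1.5 * (tt - 2), tolerance = 1e-8)
  expect_equal(tr$M_S, 2 + 0.8 * (tt - 2), tolerance = 1e-8)
  expect_equal(tr$M_R, 3 + 0.3 * (tt - 2), tolerance = 1e-8)
})

test_that("whole-plant biomass equals the organ sum and output grid is stable", {
  for (p in default_qtl_params()) {
    tt <- seq(2, 7, length.out = 11)
    tr <- solve_trajectory(p, tt)
    expect_equal(tr$W, tr$M_L + tr$M_S + tr$M_R, tolerance = 1e-9)
    # refinement of the requested grid does not change the solution
    tr2 <- solve_trajectory(p, sort(unique(c(tt, seq(2, 7, length.out = 41)))))
    expect_equal(tr2$M_S[match(tt, tr2$time)], tr$M_S, tolerance = 1e-7)
    expect_true(all(tr$M_L > 0 & tr$M_S > 0 & tr$M_R > 0))
  }
})

test_that("reference genotype curves have the reported qualitative shape", {
  # stem non-decreasing; leaf and root decelerate late in the season
  for (p in default_qtl_params()) {
    tr <- solve_trajectory(p, seq(2, 7, length.out = 51))
    expect_true(all(diff(tr$M_S) > 0))
    early_rate <- diff(tr$M_L)[2] / diff(tr$time)[2]
    late_rate <- diff(tr$M_L)[49] / diff(tr$time)[49]
    expect_lt(late_rate, early_rate / 2)
    expect_lt(diff(tr$M_R)[49], diff(tr$M_R)[2])
  }
})

test_that("organs above their quasi-equilibrium decline then stabilize", {
  # gamma-driven senescence: starting above the equilibrium manifold the
  # leaf pool loses mass before tracking whole-plant growth again
  p <- ode_params(0.5, 0.1, 1.0, 0.5, 0.05, 0.5, 0.2, 1.0,
                  init_L = 10, init_S = 1, init_R = 8)
  tr <- solve_trajectory(p, seq(0, 10, length.out = 41))
  expect_lt(min(diff(tr$M_L)[1:5]), 0)     # initial decline
  expect_lt(tr$M_L[10], tr$M_L[1])
  expect_true(all(diff(tr$M_S) > 0))
})

test_that("partition fractions sum to one and stem share rises", {
  p <- default_qtl_params()[[1]]
  tr <- solve_trajectory(p, seq(2, 7, length.out = 21))
  fr <- partition_fractions(tr)
  expect_equal(fr$frac_L + fr$frac_S + fr$frac_R, rep(1, 21),
               tolerance = 1e-12)
  expect_true(all(diff(fr$frac_S)[5:20] > 0))
  eq <- partition_fractions(tibble::tibble(time = 1, M_L = 2, M_S = 2,
                                           M_R = 2))
  expect_equal(unlist(eq[1, 2:4]), c(frac_L = 1, frac_S = 1, frac_R = 1) / 3)
})

test_that("solver accuracy is within tolerance of a refined solve", {
  p <- default_qtl_params()[[2]]
  tt <- c(2, 3, 5, 7)
  a <- solve_trajectory(p, tt)
  # halved tolerances via a fine manual integration using deSolve directly
  rhs <- function(t, y, pp) list(unname(ode_rhs(y, pp)))
  b <- deSolve::ode(c(p$init_L, p$init_S, p$init_R), tt, rhs, p,
                    rtol = 1e-11, atol = 1e-13)
  expect_equal(a$M_L, b[, 2], tolerance = 1e-6)
  expect_equal(a$M_R, b[, 4], tolerance = 1e-6)
})
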