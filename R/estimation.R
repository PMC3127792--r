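#' Residual noise model
#'
#' Diagonal, trait-specific, time-constant residual variances, optionally
#' with an AR(1) correlation per trait across a line's ordered measurements.
#'
#' @param sigma2 Length-3 positive variances (g^2) for leaf, stem, root.
#' @param rho Length-3 AR(1) correlations in (-1, 1); default 0 (white noise).
#' @return A list of class `sm_noise`.
#' @export
noise_model <- function(sigma2, rho = c(0, 0, 0)) {
  sigma2 <- rep_len(as.numeric(sigma2), 3)
  rho <- rep_len(as.numeric(rho), 3)
  if (any(sigma2 <= 0)) stop("Variances must be positive.", call. = FALSE)
  if (any(abs(rho) >= 1)) stop("|rho| must be < 1.", call. = FALSE)
  structure(list(sigma2 = sigma2, rho = rho), class = "sm_noise")
}

#' Genotype-mixture log-likelihood of longitudinal biomass data
#'
#' Evaluates \eqn{\sum_i \log \sum_j \omega_{j|i} f_j(z_i)} where
#' \eqn{f_j} is the multivariate normal density of RIL i's stacked
#' leaf/stem/root observations about genotype j's mean curves, with
#' diagonal (or per-trait AR(1)) covariance. Ragged, progeny-specific time
#' grids are supported; rows with non-finite phenotypes are excluded with a
#' message.
#'
#' @param y Phenotypes ([trait_series()]).
#' @param omega `n x J` conditional genotype probabilities (rows matching
#'   `unique(y$ril)`).
#' @param mu Genotype mean curves: a tibble `genotype`, `time`, `leaf`,
#'   `stem`, `root` covering every observed time (e.g. from
#'   [fitted_curves()]).
#' @param psi A [noise_model()].
#' @return The log-likelihood (scalar) with attribute `"posterior"`, the
#'   `n x J` posterior genotype probabilities.
#' @export
mixture_loglik <- function(y, omega, mu, psi) {
  stopifnot(inherits(psi, "sm_noise"))
  y <- trait_series(y)
  bad <- !stats::complete.cases(y[, c("leaf", "stem", "root")]) |
    !is.finite(y$time)
  if (any(bad)) {
    message("Excluding ", sum(bad), " phenotype row(s) with non-finite values.")
    y <- y[!bad, ]
  }
  rils <- unique(y$ril)
  omega <- align_weights(omega, rils)
  J <- ncol(omega)
  stopifnot(all(c("genotype", "time", "leaf", "stem", "root") %in% names(mu)))
  lq <- matrix(0, length(rils), J)
  for (i in seq_along(rils)) {
    yi <- y[y$ril == rils[i], ]
    for (j in seq_len(J)) {
      muj <- mu[mu$genotype == j, ]
      idx <- match(yi$time, muj$time)
      if (anyNA(idx)) {
        stop("Mean curves do not cover all observed times.", call. = FALSE)
      }
      ll <- 0
      for (k in 1:3) {
        tr <- c("leaf", "stem", "root")[k]
        e <- yi[[tr]] - muj[[tr]][idx]
        m <- length(e)
        if (psi$rho[k] == 0 || m == 1) {
          ll <- ll - 0.5 * sum(e^2) / psi$sigma2[k] -
            0.5 * m * log(2 * pi * psi$sigma2[k])
        } else {
          Rm <- psi$rho[k]^abs(outer(seq_len(m), seq_len(m), "-"))
          Sm <- psi$sigma2[k] * Rm
          ll <- ll - 0.5 * drop(e %*% solve(Sm, e)) -
            0.5 * (m * log(2 * pi) + determinant(Sm)$modulus)
        }
      }
      lq[i, j] <- ll
    }
  }
  lw <- log(omega)
  lw[omega == 0] <- -Inf
  a <- lq + lw
  m <- apply(a, 1, max)
  lnL <- sum(m + log(rowSums(exp(a - m))))
  post <- exp(a - m) / rowSums(exp(a - m))
  attr(lnL, "posterior") <- post
  lnL
}

#' Control settings for parameter-cascading fits
#'
#' @param lambda ODE-fidelity penalty weight in the inner criterion.
#' @param basis Optional [build_basis()] object; by default the observed
#'   times refined so no knot span exceeds `max_span` days (see
#'   [refine_interior()]).
#' @param max_span Maximal knot spacing of the default fitting basis, in
#'   the data's time unit; default 1/20 of the measurement span (fine
#'   enough to resolve dynamics faster than the sampling interval).
#' @param n_starts Number of jittered multi-starts around the
#'   gradient-matching initial values.
#' @param jitter Relative log-normal jitter (alpha, gamma) and absolute
#'   normal jitter scale (beta) applied to extra starts.
#' @param cycles Outer cycles of (Theta optimization, variance EM update).
#' @param nm_maxit,bfgs_maxit Iteration caps for the Nelder-Mead stage and
#'   the quasi-Newton (analytic-gradient BFGS) refinement per cycle.
#' @param bfgs_reltol Relative log-likelihood improvement below which the
#'   quasi-Newton stage stops.
#' @param inner_maxit,inner_tol Gauss-Newton settings of the inner fit.
#' @param tol Relative log-likelihood change declaring outer convergence.
#' @param fix_sigma Optional length-3 variances held fixed (skips the EM
#'   variance update; used for noiseless/diagnostic fits).
#' @param sigma_floor Lower bound for updated variances.
#' @return A list of class `sm_control`.
#' @export
sm_control <- function(lambda = 1e2, basis = NULL, max_span = NULL,
                       n_starts = 5, jitter = 0.2, cycles = 3,
                       nm_maxit = 100, bfgs_maxit = 150, bfgs_reltol = 1e-10,
                       inner_maxit = 100, inner_tol = 1e-8, tol = 1e-8,
                       fix_sigma = NULL, sigma_floor = 1e-8) {
  structure(as.list(environment()), class = "sm_control")
}

# log-scale transform of the 8 structural parameters (alpha, gamma > 0).
#' @keywords internal
#' @noRd
theta_to_vec <- function(Theta) {
  v <- Theta
  pos <- c(1, 3, 4, 6, 8)
  v[pos, ] <- log(pmax(Theta[pos, ], 1e-8))
  as.numeric(v)
}

#' @keywords internal
#' @noRd
vec_to_theta <- function(v, J) {
  Theta <- matrix(v, nrow = 8, ncol = J)
  pos <- c(1, 3, 4, 6, 8)
  Theta[pos, ] <- exp(pmin(pmax(Theta[pos, ], -20), 20))
  bet <- c(2, 5, 7)
  Theta[bet, ] <- pmin(pmax(Theta[bet, ], -3), 3)
  rownames(Theta) <- theta_names
  Theta
}

# Gradient-matching starting values: smooth each genotype's weighted mean
# curves, then regress the smoothed derivative on powers of smoothed W.
#' @keywords internal
#' @noRd
gm_start <- function(times, ybar) {
  basis <- build_basis(times)
  parts <- basis_parts(basis, times)
  P <- crossprod(parts$dPhiQ)
  scl <- mean(diag(crossprod(parts$Phi)))
  tg <- seq(min(times), max(times), length.out = 50)
  Phig <- eval_basis(basis, tg, 0)
  dPhig <- eval_basis(basis, tg, 1)
  mu <- dmu <- matrix(0, 3, length(tg))
  for (k in 1:3) {
    M <- crossprod(parts$Phi) + 1e-3 * scl * P / mean(diag(P)) +
      1e-8 * diag(basis$R)
    ck <- solve(M, crossprod(parts$Phi, ybar[k, ]))
    mu[k, ] <- Phig %*% ck
    dmu[k, ] <- dPhig %*% ck
  }
  W <- pmax(colSums(mu), 1e-6)
  th <- numeric(8)
  # stem: log-linear allometric regression on points with positive growth
  ok <- dmu[2, ] > 1e-6
  if (sum(ok) >= 3) {
    co <- stats::coef(stats::lm(log(dmu[2, ok]) ~ log(W[ok])))
    th[4] <- exp(co[1]); th[5] <- co[2]
  } else {
    th[4] <- 1; th[5] <- 0.1
  }
  # leaf / root: profile alpha, search (beta, log gamma)
  fit_lr <- function(k) {
    obj <- function(p) {
      b <- p[1]; g <- exp(p[2])
      z <- dmu[k, ] + g * mu[k, ]
      Wb <- W^b
      a <- sum(z * Wb) / sum(Wb^2)
      if (!is.finite(a) || a <= 0) return(1e10)
      sum((dmu[k, ] - a * Wb + g * mu[k, ])^2)
    }
    op <- stats::optim(c(0.3, log(0.5)), obj, method = "Nelder-Mead",
                       control = list(maxit = 300))
    b <- op$par[1]; g <- exp(op$par[2])
    Wb <- W^b
    a <- sum((dmu[k, ] + g * mu[k, ]) * Wb) / sum(Wb^2)
    c(max(a, 1e-3), min(max(b, -0.5), 1.5), max(g, 1e-4))
  }
  th[1:3] <- fit_lr(1)
  th[6:8] <- fit_lr(3)
  th[5] <- min(max(th[5], -0.5), 1.5)
  th[4] <- max(th[4], 1e-3)
  th
}

# Shared fitting engine for M1 (J = 2) and M0 (J = 1).
#' @keywords internal
#' @noRd
fit_cascade <- function(y, omega, control = sm_control(), model = "M1",
                        theta_start = NULL, extra_starts = NULL,
                        sigma_start = NULL, quiet = TRUE) {
  if (inherits(y, "sm_fitdata")) {
    arr <- y$arr
    hash <- y$hash
    y <- y$y
  } else {
    y <- trait_series(y)
    arr <- pheno_arrays(y)
    hash <- rlang::hash(list(y$ril, y$time, y$leaf, y$stem, y$root))
  }
  omega <- align_weights(omega, arr$rils)
  J <- ncol(omega)
  n <- length(arr$rils)
  basis <- control$basis
  if (is.null(basis)) {
    ms <- control$max_span
    if (is.null(ms)) ms <- diff(range(arr$times)) / 20
    basis <- build_basis(arr$times,
                         interior = refine_interior(arr$times, ms))
  }
  parts <- basis_parts(basis, arr$times)
  suff <- suff_stats(arr$Y, omega)

  # starting structural values per genotype from gradient matching
  if (is.null(theta_start)) {
    theta_start <- vapply(seq_len(J), function(j) {
      gm_start(arr$times, suff$Ybar[, , j])
    }, numeric(8))
  }
  theta_start <- theta_matrix(theta_start)

  # initial variances: residuals about the weighted per-time genotype means
  if (!is.null(sigma_start)) {
    sigma2 <- pmax(rep_len(sigma_start, 3), control$sigma_floor)
  } else if (is.null(control$fix_sigma)) {
    sigma2 <- vapply(1:3, function(k) {
      num <- 0; den <- 0
      for (j in seq_len(J)) {
        E <- sweep(arr$Y[, , k, drop = FALSE][, , 1, drop = TRUE],
                   2, suff$Ybar[k, , j])
        if (n == 1) E <- matrix(E, nrow = 1)
        num <- num + sum(omega[, j] * rowSums(E^2, na.rm = TRUE))
        den <- den + sum(omega[, j] * rowSums(is.finite(E)))
      }
      max(num / den, control$sigma_floor)
    }, numeric(1))
  } else {
    sigma2 <- rep_len(control$fix_sigma, 3)
  }

  # multi-start design: the gradient-matching values, two elimination-rate
  # rescalings covering the fast/slow-equilibration ridge the criterion is
  # known to have, then random jitters; callers may append further starts
  # (e.g. the genome scan's null-fit start, which floors the LR at zero)
  starts <- list(theta_start)
  if (control$n_starts > 1) {
    for (s in seq_len(control$n_starts - 1)) {
      jit <- theta_start
      if (s == 1 || s == 2) {
        fac <- if (s == 1) 5 else 1 / 5
        jit[c(3, 8), ] <- jit[c(3, 8), ] * fac
      } else {
        pos <- c(1, 3, 4, 6, 8)
        jit[pos, ] <- jit[pos, ] *
          exp(matrix(stats::rnorm(length(pos) * J, 0, control$jitter),
                     length(pos), J))
        bet <- c(2, 5, 7)
        jit[bet, ] <- jit[bet, ] +
          matrix(stats::rnorm(length(bet) * J, 0,
                              control$jitter * (abs(jit[bet, ]) + 0.05)),
                 length(bet), J)
      }
      starts[[s + 1]] <- jit
    }
  }
  if (J > 1 && control$n_starts > 1) {
    # collapsed start (all genotypes share the pooled values): keeps the
    # full model from converging below its nested single-curve submodel
    starts[[length(starts) + 1]] <-
      matrix(rowMeans(theta_start), 8, J)
  }
  if (!is.null(extra_starts)) {
    starts <- c(starts, lapply(extra_starts, theta_matrix))
  }

  # one optimization stage: BFGS (analytic IFT gradient) cycles with
  # EM variance updates, on a given basis / penalty weight
  run_stage <- function(Theta0, sigma2, basis_s, parts_s, lambda_s,
                        nm_it, bfgs_it, cycles_s, C0 = NULL) {
    env <- new.env()
    env$C <- C0
    env$last_v <- NULL
    negll <- function(v) {
      Theta <- vec_to_theta(v, J)
      c0 <- if (is.null(env$C)) init_coefs(parts_s, suff, sigma2,
                                           lambda_s) else env$C
      fit <- cpp_inner_fit(parts_s$Phi, parts_s$PhiQ, parts_s$dPhiQ,
                           basis_s$quad_w, suff$A, suff$Ybar, sigma2, Theta,
                           lambda_s, c0, as.integer(control$inner_maxit),
                           control$inner_tol)
      env$C <- fit$C
      R <- basis_s$R
      mu <- array(0, dim = c(length(arr$times), 3, J))
      for (j in seq_len(J)) {
        mu[, , j] <- parts_s$Phi %*% matrix(fit$C[, j], R, 3)
      }
      ml <- cpp_mixture_loglik(arr$Y, omega, mu, sigma2)
      env$ml <- ml
      env$last_v <- v
      if (!is.finite(ml$loglik)) return(1e10)
      -ml$loglik
    }
    # analytic gradient of -lnL via the implicit-function-theorem
    # derivative of the profiled coefficients, chained through the
    # log transform of the positive parameters
    grad_negll <- function(v) {
      if (is.null(env$last_v) || !identical(v, env$last_v)) negll(v)
      Theta <- vec_to_theta(v, J)
      gr <- cpp_profile_grad(parts_s$Phi, parts_s$PhiQ, parts_s$dPhiQ,
                             basis_s$quad_w, suff$A, suff$Ybar, sigma2,
                             Theta, lambda_s, env$C, env$ml$dmu)$grad
      pos <- c(1, 3, 4, 6, 8)
      gr[pos, ] <- gr[pos, ] * Theta[pos, ]  # d theta / d log theta
      -as.numeric(gr)
    }
    v <- theta_to_vec(Theta0)
    lnL_prev <- -Inf
    for (cy in seq_len(cycles_s)) {
      if (nm_it > 0) {
        op <- stats::optim(v, negll, method = "Nelder-Mead",
                           control = list(maxit = nm_it))
        v <- op$par
      }
      if (bfgs_it > 0) {
        op <- try(stats::optim(v, negll, gr = grad_negll, method = "BFGS",
                               control = list(maxit = bfgs_it,
                                              reltol = control$bfgs_reltol)),
                  silent = TRUE)
        if (!inherits(op, "try-error") && op$value <= negll(v)) v <- op$par
      }
      lnL <- -negll(v)
      if (is.null(control$fix_sigma)) {
        sigma2 <- pmax(env$ml$ss / env$ml$nobs, control$sigma_floor)
        lnL <- -negll(v)  # refresh at updated variances
      }
      if (is.finite(lnL_prev) &&
          abs(lnL - lnL_prev) < control$tol * (1 + abs(lnL))) break
      lnL_prev <- lnL
    }
    list(v = v, sigma2 = sigma2, loglik = lnL, C = env$C, cycles = cy)
  }

  results <- list()
  for (s in seq_along(starts)) {
    res <- try(run_stage(starts[[s]], sigma2, basis, parts, control$lambda,
                         control$nm_maxit, control$bfgs_maxit,
                         control$cycles), silent = TRUE)
    if (!inherits(res, "try-error") && is.finite(res$loglik)) {
      results[[length(results) + 1]] <- res
    }
  }
  if (length(results) == 0) {
    stop("All ", length(starts), " starts failed for model ", model, ".",
         call. = FALSE)
  }
  best <- results[[which.max(vapply(results, `[[`, 0, "loglik"))]]
  Theta <- vec_to_theta(best$v, J)
  coefs <- structure(list(C = best$C, basis = basis,
                          lambda = control$lambda, times = arr$times),
                     class = "sm_coefficients")
  mu0 <- fitted_curves(coefs, min(arr$times))
  params <- lapply(seq_len(J), function(j) {
    as_ode_params(c(as.list(stats::setNames(Theta[, j], theta_names)),
                    list(init_L = max(mu0$leaf[j], 1e-6),
                         init_S = max(mu0$stem[j], 1e-6),
                         init_R = max(mu0$root[j], 1e-6))))
  })
  structure(list(
    model = model,
    params = params,
    theta = Theta,
    psi = noise_model(best$sigma2),
    loglik = best$loglik,
    coefs = coefs,
    omega = omega,
    n = n,
    times = arr$times,
    n_starts_ok = length(results),
    start_logliks = vapply(results, `[[`, 0, "loglik"),
    data_hash = hash,
    control = control
  ), class = "sm_fit")
}

#' Fit the two-genotype (full, M1) systems-mapping model at a position
#'
#' Maximizes the genotype-mixture log-likelihood over the two genotypes'
#' structural ODE parameters and the residual variances, with the spline
#' coefficients profiled out via the ODE-penalized [inner_fit()] (parameter
#' cascading). Multi-start: the gradient-matching initial values plus
#' jittered replicates; the best final log-likelihood is kept.
#'
#' @param y Phenotypes ([trait_series()]).
#' @param omega `n x 2` conditional QTL genotype probabilities from
#'   [qtl_genotype_probs()].
#' @param control An [sm_control()] list.
#' @param theta_start Optional `8 x 2` warm-start matrix (e.g. from the
#'   neighbouring scan position); suppresses gradient matching.
#' @param extra_starts Optional list of further `8 x J` starting matrices
#'   appended to the multi-start set.
#' @param sigma_start Optional length-3 initial residual variances (e.g.
#'   the null fit's estimates during a scan); still re-estimated.
#' @return An object of class `sm_fit`: per-genotype [ode_params()]
#'   (`params`), the `8 x 2` estimate matrix (`theta`), the fitted
#'   [noise_model()] (`psi`), `loglik`, the spline coefficients, and
#'   convergence diagnostics. Methods: [tidy()], [glance()], `autoplot()`.
#' @export
fit_m1 <- function(y, omega, control = sm_control(), theta_start = NULL,
                   extra_starts = NULL, sigma_start = NULL) {
  stopifnot(ncol(as.matrix(omega)) == 2)
  fit_cascade(y, omega, control, model = "M1", theta_start = theta_start,
              extra_starts = extra_starts, sigma_start = sigma_start)
}

#' Fit the single-curve (reduced, M0) model
#'
#' The no-QTL null: one set of ODE parameters for the whole population
#' (the mixture collapses to a single multivariate normal).
#'
#' @inheritParams fit_m1
#' @return An `sm_fit` with `model = "M0"` and one genotype.
#' @export
fit_m0 <- function(y, control = sm_control(), theta_start = NULL) {
  if (!inherits(y, "sm_fitdata")) y <- sm_fit_data(y)
  n <- length(y$arr$rils)
  fit_cascade(y, matrix(1, n, 1), control, model = "M0",
              theta_start = theta_start)
}

#' Likelihood-ratio statistic between the full and reduced fits
#'
#' `LR = 2 (lnL_M1 - lnL_M0)`. Small negative values (optimizer tolerance)
#' are clamped to zero with a warning; the two fits must come from the same
#' data.
#'
#' @param m1,m0 `sm_fit` objects from [fit_m1()] and [fit_m0()].
#' @param tol Clamping tolerance for small negative values.
#' @return The LR statistic (scalar).
#' @export
lr_statistic <- function(m1, m0, tol = 1e-4) {
  stopifnot(inherits(m1, "sm_fit"), inherits(m0, "sm_fit"))
  if (!identical(m1$data_hash, m0$data_hash)) {
    stop("The two fits were not computed on the same data.", call. = FALSE)
  }
  lr <- 2 * (m1$loglik - m0$loglik)
  if (lr < 0) {
    if (lr < -max(tol, 1e-12)) {
      warning("Negative LR (", format(lr, digits = 4),
              ") clamped to 0; the full fit under-converged.", call. = FALSE)
    }
    lr <- 0
  }
  lr
}

#' Parametric-bootstrap standard errors of the structural estimates
#'
#' Simulates `B` datasets from the fitted model (genotype drawn from the
#' conditional probabilities, phenotype = fitted genotype mean curves plus
#' Gaussian noise at the observed design), refits each, and reports the
#' standard deviation of the estimates.
#'
#' @param fit A converged `sm_fit`.
#' @param y The original phenotypes (defines the measurement design).
#' @param omega Conditional genotype probabilities used in the fit.
#' @param B Number of bootstrap replicates (>= 2).
#' @param control Refitting control; defaults to the fit's own control with
#'   a single warm start.
#' @param max_fail Maximum tolerated fraction of non-converged replicates.
#' @return A tibble `genotype`, `term`, `estimate`, `se` with attribute
#'   `"replicates"` (the B x (8J) matrix of estimates).
#' @export
bootstrap_se <- function(fit, y, omega, B = 100, control = NULL,
                         max_fail = 0.2) {
  stopifnot(inherits(fit, "sm_fit"), B >= 2)
  y <- trait_series(y)
  arr <- pheno_arrays(y)
  omega <- align_weights(omega, arr$rils)
  J <- ncol(omega)
  if (is.null(control)) {
    control <- fit$control
    control$n_starts <- 1
    control$cycles <- max(1, control$cycles - 1)
  }
  mu <- mu_cube(fit$coefs, arr$times)
  ests <- matrix(NA_real_, B, 8 * J)
  fails <- 0
  for (b in seq_len(B)) {
    g <- apply(omega, 1, function(w) sample.int(J, 1, prob = w))
    Yb <- arr$Y
    for (k in 1:3) {
      mk <- t(mu[, k, ])[g, , drop = FALSE]  # n x T genotype means
      noise <- matrix(stats::rnorm(length(mk), 0,
                                   sqrt(fit$psi$sigma2[k])),
                      nrow = nrow(mk))
      Yk <- mk + noise
      Yk[!is.finite(arr$Y[, , k, drop = FALSE][, , 1, drop = TRUE])] <- NaN
      Yb[, , k] <- Yk
    }
    yb <- array_to_pheno(Yb, arr$rils, arr$times)
    fb <- try(fit_cascade(yb, omega, control, model = fit$model,
                          theta_start = fit$theta), silent = TRUE)
    if (inherits(fb, "try-error")) { fails <- fails + 1; next }
    ests[b, ] <- as.numeric(fb$theta)
  }
  if (fails / B > max_fail) {
    stop(fails, " of ", B, " bootstrap replicates failed to converge.",
         call. = FALSE)
  }
  se <- apply(ests, 2, stats::sd, na.rm = TRUE)
  out <- tibble::tibble(
    genotype = rep(seq_len(J), each = 8),
    term = rep(theta_names, J),
    estimate = as.numeric(fit$theta),
    se = se
  )
  attr(out, "replicates") <- ests
  out
}

#' Precompute the fitting arrays for repeated fits on one dataset
#'
#' Scans and permutation loops fit the same phenotypes many times; this
#' captures the validated table, its array form and its hash once so each
#' position fit skips the reshaping.
#'
#' @param y Phenotypes ([trait_series()]).
#' @return An object of class `sm_fitdata` accepted by [fit_m1()],
#'   [fit_m0()] and [genome_scan()] wherever phenotypes are expected.
#' @export
sm_fit_data <- function(y) {
  y <- trait_series(y)
  structure(list(y = y, arr = pheno_arrays(y),
                 hash = rlang::hash(list(y$ril, y$time, y$leaf, y$stem,
                                         y$root))),
            class = "sm_fitdata")
}

# inverse of pheno_arrays for simulated arrays
#' @keywords internal
#' @noRd
array_to_pheno <- function(Y, rils, times) {
  n <- length(rils); T <- length(times)
  df <- tibble::tibble(
    ril = rep(rils, times = T),
    time = rep(times, each = n),
    leaf = as.numeric(Y[, , 1]),
    stem = as.numeric(Y[, , 2]),
    root = as.numeric(Y[, , 3])
  )
  df <- df[is.finite(df$leaf) | is.finite(df$stem) | is.finite(df$root), ]
  trait_series(df)
}
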