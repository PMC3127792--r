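#' ODE-penalized inner fit of spline coefficients
#'
#' The inner level of parameter cascading: given structural ODE parameters
#' for each QTL genotype, estimates the basis coefficients of the
#' genotype-specific mean curves by minimizing
#' \deqn{U(c \mid \Theta) = \sum_k \sum_j \sum_i \omega_{j|i} \sum_t
#'   \frac{[y_{ki}(t) - \phi(t)^\top c_{kj}]^2}{\sigma_k^2}
#'   + \lambda \sum_k \sum_j \int
#'   \left[\frac{d\mu_{kj}}{dt} - f_k(\mu_j(t); \Theta_j)\right]^2 dt,}
#' the integral evaluated by Gauss-Legendre quadrature per knot span and the
#' minimization by damped Gauss-Newton. The penalty ties each genotype's
#' fitted curves to the biomass-partitioning system, which is what makes
#' \eqn{\Theta} identifiable from the curves.
#'
#' @param y Phenotypes ([trait_series()] long tibble).
#' @param weights `n x J` matrix of conditional genotype probabilities
#'   (rows matching `unique(y$ril)`); use a column of ones for a
#'   single-population fit.
#' @param theta Structural parameters: one [ode_params()] per genotype (list
#'   of length J) or an `8 x J` matrix.
#' @param basis A [build_basis()] object (defaults to the saturated basis on
#'   the observed times).
#' @param lambda ODE-fidelity penalty weight (>= 0).
#' @param sigma2 Residual variances (g^2) per trait, length 3.
#' @param c0 Optional warm-start coefficient matrix (`3R x J`).
#' @param maxit,tol Gauss-Newton iteration cap and gradient-norm tolerance.
#' @return An object of class `sm_coefficients`: coefficient matrix `C`
#'   (`3R x J`, leaf/stem/root blocks), the basis, the attained criterion
#'   value per genotype, and convergence diagnostics.
#' @export
inner_fit <- function(y, weights, theta, basis = NULL, lambda = 1e2,
                      sigma2 = c(1, 1, 1), c0 = NULL, maxit = 100,
                      tol = 1e-8) {
  stopifnot(lambda >= 0, all(sigma2 > 0))
  arr <- pheno_arrays(y)
  Theta <- theta_matrix(theta)
  J <- ncol(Theta)
  weights <- align_weights(weights, arr$rils)
  if (ncol(weights) != J) {
    stop("`weights` must be ", length(arr$rils), " x ", J, ".", call. = FALSE)
  }
  if (is.null(basis)) basis <- build_basis(arr$times)
  parts <- basis_parts(basis, arr$times)
  suff <- suff_stats(arr$Y, weights)
  if (is.null(c0)) c0 <- init_coefs(parts, suff, sigma2, lambda)
  fit <- cpp_inner_fit(parts$Phi, parts$PhiQ, parts$dPhiQ, basis$quad_w,
                       suff$A, suff$Ybar, sigma2, Theta, lambda, c0,
                       as.integer(maxit), tol)
  if (!isTRUE(fit$converged) && max(fit$gnorm) > 1e-3 * (1 + max(abs(fit$obj)))) {
    warning("Inner fit did not reach the gradient tolerance (max |g| = ",
            format(max(fit$gnorm), digits = 3), ").", call. = FALSE)
  }
  structure(list(C = fit$C, basis = basis, obj = as.numeric(fit$obj),
                 gnorm = as.numeric(fit$gnorm), iters = fit$iters,
                 converged = isTRUE(fit$converged), lambda = lambda,
                 times = arr$times),
            class = "sm_coefficients")
}

# Design matrices at the data times and quadrature nodes.
#' @keywords internal
#' @noRd
basis_parts <- function(basis, times) {
  list(Phi = eval_basis(basis, times, 0),
       PhiQ = eval_basis(basis, basis$quad_x, 0),
       dPhiQ = eval_basis(basis, basis$quad_x, 1))
}

# Weighted per-time sufficient statistics: A[t, j] = sum_i w_ij 1(obs),
# Ybar[k, t, j] = weighted mean of trait k at time t under genotype j.
#' @keywords internal
#' @noRd
suff_stats <- function(Y, weights) {
  n <- dim(Y)[1]; T <- dim(Y)[2]; J <- ncol(weights)
  A <- matrix(0, T, J)
  Ybar <- array(0, dim = c(3, T, J))
  for (j in seq_len(J)) {
    for (k in 1:3) {
      Yk <- Y[, , k, drop = FALSE][, , 1]
      if (n == 1) Yk <- matrix(Yk, nrow = 1)
      obs <- is.finite(Yk)
      w <- weights[, j]
      Aj <- colSums(obs * w)
      B <- colSums(ifelse(obs, Yk, 0) * w)
      Ybar[k, , j] <- ifelse(Aj > 0, B / Aj, 0)
      if (k == 1) A[, j] <- Aj
    }
  }
  list(A = A, Ybar = Ybar)
}

# Ridge-penalized least-squares start for the coefficients (data fit with a
# mild first-derivative roughness penalty; no ODE term).
#' @keywords internal
#' @noRd
init_coefs <- function(parts, suff, sigma2, lambda) {
  R <- ncol(parts$Phi); T <- nrow(parts$Phi); J <- ncol(suff$A)
  P <- crossprod(parts$dPhiQ, parts$dPhiQ)
  C0 <- matrix(0, 3 * R, J)
  for (j in seq_len(J)) {
    for (k in 1:3) {
      D <- suff$A[, j] / sigma2[k]
      M <- crossprod(parts$Phi, D * parts$Phi) + 1e-4 * P + 1e-8 * diag(R)
      b <- crossprod(parts$Phi, D * suff$Ybar[k, , j])
      C0[((k - 1) * R + 1):(k * R), j] <- solve(M, b)
    }
  }
  C0
}

#' Evaluate fitted genotype mean curves
#'
#' @param coefs An [inner_fit()] result.
#' @param t Times at which to evaluate (within the basis range).
#' @return Tibble `genotype`, `time`, `leaf`, `stem`, `root`.
#' @export
fitted_curves <- function(coefs, t = coefs$times) {
  stopifnot(inherits(coefs, "sm_coefficients"))
  Phi <- eval_basis(coefs$basis, t, 0)
  R <- coefs$basis$R
  J <- ncol(coefs$C)
  purrr::map_dfr(seq_len(J), function(j) {
    tibble::tibble(
      genotype = j, time = t,
      leaf = as.numeric(Phi %*% coefs$C[1:R, j]),
      stem = as.numeric(Phi %*% coefs$C[(R + 1):(2 * R), j]),
      root = as.numeric(Phi %*% coefs$C[(2 * R + 1):(3 * R), j])
    )
  })
}

# mu cube (T x 3 x J) at given times, for the likelihood core.
#' @keywords internal
#' @noRd
mu_cube <- function(coefs, t) {
  Phi <- eval_basis(coefs$basis, t, 0)
  R <- coefs$basis$R
  J <- ncol(coefs$C)
  mu <- array(0, dim = c(length(t), 3, J))
  for (j in seq_len(J)) {
    for (k in 1:3) {
      mu[, k, j] <- Phi %*% coefs$C[((k - 1) * R + 1):(k * R), j]
    }
  }
  mu
}
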