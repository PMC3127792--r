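#' ODE parameters for allometric biomass partitioning
#'
#' One genotype's parameter set for the coupled leaf/stem/root biomass
#' system
#' \deqn{dM_L/dt = \alpha_L W^{\beta_L} - \gamma_L M_L, \quad
#'       dM_S/dt = \alpha_S W^{\beta_S}, \quad
#'       dM_R/dt = \alpha_R W^{\beta_R} - \gamma_R M_R,}
#' with whole-plant biomass \eqn{W = M_L + M_S + M_R}. The `alpha` are
#' allometric constants (g^(1-beta) per season time unit), the `beta`
#' dimensionless scaling exponents of organ growth on whole-plant biomass,
#' and the `gamma` first-order elimination rates (per time unit) of ageing
#' leaves and roots (the stem does not senesce). `init_*` are auxiliary
#' initial organ biomasses (g) at the start of the modelled season. In the
#' package's reference study conditions one time unit corresponds to
#' roughly ten days of the emulated field protocol.
#'
#' @param alpha_L,beta_L,gamma_L Leaf production constant, exponent, loss rate.
#' @param alpha_S,beta_S Stem production constant and exponent.
#' @param alpha_R,beta_R,gamma_R Root production constant, exponent, loss rate.
#' @param init_L,init_S,init_R Initial organ biomasses (g), all positive.
#' @return A named list of class `sm_ode_params`.
#' @export
ode_params <- function(alpha_L, beta_L, gamma_L, alpha_S, beta_S,
                       alpha_R, beta_R, gamma_R,
                       init_L = 0.5, init_S = 0.3, init_R = 0.2) {
  p <- list(alpha_L = alpha_L, beta_L = beta_L, gamma_L = gamma_L,
            alpha_S = alpha_S, beta_S = beta_S,
            alpha_R = alpha_R, beta_R = beta_R, gamma_R = gamma_R,
            init_L = init_L, init_S = init_S, init_R = init_R)
  if (any(!vapply(p, is.numeric, TRUE)) || any(!is.finite(unlist(p)))) {
    stop("All ODE parameters must be finite numerics.", call. = FALSE)
  }
  if (alpha_L <= 0 || alpha_S <= 0 || alpha_R <= 0) {
    stop("alpha parameters must be positive.", call. = FALSE)
  }
  if (gamma_L < 0 || gamma_R < 0) {
    stop("gamma parameters must be non-negative.", call. = FALSE)
  }
  if (init_L <= 0 || init_S <= 0 || init_R <= 0) {
    stop("Initial biomasses must be positive.", call. = FALSE)
  }
  structure(p, class = "sm_ode_params")
}

#' Coerce a vector/row to `sm_ode_params`
#' @param x A named numeric vector, list or one-row data frame holding at
#'   least the eight structural parameters.
#' @return An `sm_ode_params` object.
#' @export
as_ode_params <- function(x) {
  x <- as.list(x)
  do.call(ode_params, x[intersect(names(x), names(formals(ode_params)))])
}

theta_names <- c("alpha_L", "beta_L", "gamma_L", "alpha_S", "beta_S",
                 "alpha_R", "beta_R", "gamma_R")

#' Right-hand side of the biomass partitioning system
#'
#' @param state Numeric vector `c(M_L, M_S, M_R)` of strictly positive
#'   organ biomasses (g).
#' @param params An [ode_params()] object (or coercible).
#' @return Named derivatives (g per time unit) for the three organs; their
#'   sum is `dW/dt` by construction.
#' @export
ode_rhs <- function(state, params) {
  params <- as_ode_params(params)
  if (length(state) != 3 || any(!is.finite(state)) || any(state <= 0)) {
    stop("`state` must be three strictly positive biomasses.", call. = FALSE)
  }
  W <- sum(state)
  c(M_L = params$alpha_L * W^params$beta_L - params$gamma_L * state[[1]],
    M_S = params$alpha_S * W^params$beta_S,
    M_R = params$alpha_R * W^params$beta_R - params$gamma_R * state[[3]])
}

#' Solve a genotype's biomass trajectory
#'
#' Integrates the partitioning system with `deSolve::ode` (lsoda: adaptive
#' step with automatic stiff/non-stiff switching; rtol 1e-8, atol 1e-10)
#' and returns organ biomasses interpolated at the requested times.
#'
#' @param params An [ode_params()] object; `init_*` give the state at `t0`.
#' @param times Strictly increasing output times; `t0` defaults to
#'   `times[1]`.
#' @param t0 Time at which `init_*` apply.
#' @return A tibble of class `sm_trajectory`: `time`, `M_L`, `M_S`, `M_R`,
#'   `W`.
#' @examples
#' p <- ode_params(2.55, 0.10, 0.31, 0.98, 0.04, 1.11, 0.51, 2.18)
#' solve_trajectory(p, c(2, 2.2, 2.5, 3, 4.5, 7))
#' @export
solve_trajectory <- function(params, times, t0 = times[1]) {
  params <- as_ode_params(params)
  stopifnot(length(times) >= 1, all(diff(times) > 0), times[1] >= t0)
  y0 <- c(params$init_L, params$init_S, params$init_R)
  tt <- unique(c(t0, times))
  rhs <- function(t, y, p) {
    W <- max(sum(y), 1e-12)
    list(c(p$alpha_L * W^p$beta_L - p$gamma_L * y[1],
           p$alpha_S * W^p$beta_S,
           p$alpha_R * W^p$beta_R - p$gamma_R * y[3]))
  }
  sol <- try(deSolve::ode(y = y0, times = tt, func = rhs, parms = params,
                          rtol = 1e-8, atol = 1e-10), silent = TRUE)
  if (inherits(sol, "try-error") || any(!is.finite(sol)) ||
      nrow(sol) < length(tt)) {
    stop("ODE integration failed for parameters: ",
         paste(sprintf("%s=%.4g", theta_names, unlist(params[theta_names])),
               collapse = ", "), call. = FALSE)
  }
  sol <- sol[match(times, tt), , drop = FALSE]
  out <- tibble::tibble(time = times,
                        M_L = sol[, 2], M_S = sol[, 3], M_R = sol[, 4])
  out$W <- out$M_L + out$M_S + out$M_R
  class(out) <- c("sm_trajectory", class(out))
  out
}

#' Time-resolved biomass partition fractions
#'
#' @param traj A trajectory from [solve_trajectory()] (or any data frame
#'   with `time`, `M_L`, `M_S`, `M_R`).
#' @return Tibble `time`, `frac_L`, `frac_S`, `frac_R`; rows sum to 1.
#' @export
partition_fractions <- function(traj) {
  stopifnot(all(c("time", "M_L", "M_S", "M_R") %in% names(traj)))
  W <- traj$M_L + traj$M_S + traj$M_R
  if (any(W <= 0)) stop("Whole-plant biomass must be positive.", call. = FALSE)
  tibble::tibble(time = traj$time,
                 frac_L = traj$M_L / W,
                 frac_S = traj$M_S / W,
                 frac_R = traj$M_R / W)
}
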