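#' Information-bound design analysis for a simulation study
#'
#' Computes, for each genotype, the Fisher-information lower bounds on the
#' standard deviations of the structural parameter estimates implied by a
#' measurement design: sensitivities of the mean curves to the eight
#' structural parameters and the three auxiliary initial states (central
#' finite differences through the ODE solver), weighted by the residual
#' precision from the heritability calibration, inverted to the CRLB.
#' No estimator under the white-noise model can beat these bounds; they
#' are the package's instrument for choosing measurement occasions (see
#' the vignette).
#'
#' @param params_pair List of two generating [ode_params()].
#' @param times Measurement occasions.
#' @param h2 Per-trait heritability at the middle measurement time used to
#'   calibrate the residual variances (see [heritability_to_sigma()]).
#' @param n Number of RILs (split evenly between the genotype classes).
#' @param t_star Calibration time passed to [heritability_to_sigma()].
#' @return A tibble `genotype`, `term`, `sd_bound` for the 8 structural
#'   parameters per genotype.
#' @examples
#' \donttest{
#' design_information(default_qtl_params(), c(2, 2.2, 2.5, 3, 4.5, 7))
#' }
#' @export
design_information <- function(params_pair, times, h2 = 0.05, n = 184,
                               t_star = NULL) {
  stopifnot(length(params_pair) == 2, n >= 4)
  sig2 <- heritability_to_sigma(params_pair, times, h2, t_star = t_star)
  out <- purrr::map_dfr(1:2, function(j) {
    p0 <- unlist(as_ode_params(params_pair[[j]]))
    f <- function(pv) {
      tr <- solve_trajectory(as_ode_params(as.list(pv)), times)
      c(tr$M_L, tr$M_S, tr$M_R)
    }
    Jm <- vapply(seq_along(p0), function(i) {
      h <- 1e-4 * max(abs(p0[i]), 1e-2)
      pa <- p0; pa[i] <- p0[i] + h
      pb <- p0; pb[i] <- p0[i] - h
      (f(pa) - f(pb)) / (2 * h)
    }, numeric(3 * length(times)))
    w <- rep(as.numeric(sig2)^-1, each = length(times)) * (n / 2)
    FIM <- crossprod(Jm, w * Jm)
    V <- solve(FIM + diag(1e-12, length(p0)))
    tibble::tibble(genotype = j, term = theta_names,
                   sd_bound = sqrt(pmax(diag(V)[1:8], 0)))
  })
  out
}
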