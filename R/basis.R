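#' Build a cubic B-spline basis over the measurement season
#'
#' Following the saturated-knot strategy, one knot is placed at every
#' distinct measurement time (a roughness/ODE-fidelity penalty controls
#' overfitting), with full-multiplicity boundary knots. The number of basis
#' functions is `R = #interior knots + order`.
#'
#' @param times Distinct measurement times (days); at least `order` distinct
#'   values are required.
#' @param interior Optional explicit interior knots; defaults to the
#'   interior observed times (saturated).
#' @param order Spline order (4 = cubic, the default).
#' @param n_quad Gauss-Legendre nodes per knot span used for penalty
#'   quadrature (default 5).
#' @return An object of class `sm_basis`: knot vector, order, number of
#'   basis functions `R`, range, and quadrature nodes/weights.
#' @examples
#' b <- build_basis(c(0, 1, 2, 3))
#' b$R  # 6
#' @export
build_basis <- function(times, interior = NULL, order = 4, n_quad = 5) {
  times <- sort(unique(as.numeric(times)))
  if (length(times) < order) {
    stop("Need at least ", order, " distinct times to build an order-",
         order, " basis.", call. = FALSE)
  }
  rng <- range(times)
  if (is.null(interior)) {
    interior <- times[-c(1, length(times))]
  } else {
    interior <- sort(as.numeric(interior))
    if (any(interior <= rng[1]) || any(interior >= rng[2])) {
      stop("Interior knots must lie strictly inside the time range.",
           call. = FALSE)
    }
  }
  knots <- c(rep(rng[1], order), interior, rep(rng[2], order))
  spans <- sort(unique(c(rng, interior)))
  gl <- pracma::gaussLegendre(n_quad, -1, 1)
  qx <- qw <- numeric(0)
  for (s in seq_len(length(spans) - 1)) {
    a <- spans[s]; b <- spans[s + 1]
    qx <- c(qx, (b - a) / 2 * gl$x + (a + b) / 2)
    qw <- c(qw, (b - a) / 2 * gl$w)
  }
  structure(list(order = order, knots = knots, interior = interior,
                 range = rng, R = length(interior) + order,
                 quad_x = qx, quad_w = qw),
            class = "sm_basis")
}

#' Evaluate B-spline basis functions (or their first derivative)
#'
#' @param basis An [build_basis()] object.
#' @param t Evaluation times; must lie within the basis range (no
#'   extrapolation).
#' @param deriv 0 for function values, 1 for first derivatives.
#' @return A `length(t) x R` design matrix; a curve is `eval_basis(b, t) %*% c`.
#' @export
eval_basis <- function(basis, t, deriv = 0) {
  stopifnot(inherits(basis, "sm_basis"), deriv %in% c(0L, 1L))
  t <- as.numeric(t)
  if (any(t < basis$range[1]) || any(t > basis$range[2])) {
    stop("Evaluation times outside the basis range; extrapolation is not supported.",
         call. = FALSE)
  }
  splines::splineDesign(basis$knots, t, ord = basis$order,
                        derivs = rep(deriv, length(t)))
}

#' Interior knots refining the measurement grid
#'
#' Subdivides every span between consecutive measurement times into equal
#' pieces no longer than `max_span` days, so the spline space can resolve
#' dynamics faster than the sampling interval (the ODE-fidelity penalty
#' supplies the regularization that the extra knots would otherwise
#' forfeit). Used as the default fitting basis.
#'
#' @param times Measurement times.
#' @param max_span Maximal knot spacing (days).
#' @return Interior knot vector (suitable for [build_basis()]'s `interior`).
#' @export
refine_interior <- function(times, max_span = 5) {
  times <- sort(unique(as.numeric(times)))
  stopifnot(length(times) >= 2, max_span > 0)
  knots <- unlist(lapply(seq_len(length(times) - 1), function(s) {
    k <- max(1, ceiling((times[s + 1] - times[s]) / max_span))
    seq(times[s], times[s + 1], length.out = k + 1)
  }))
  setdiff(sort(unique(knots)), range(times))
}
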