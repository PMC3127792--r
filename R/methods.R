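#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a systems-mapping fit
#'
#' One row per structural parameter per genotype, broom-style.
#'
#' @param x An `sm_fit`.
#' @param ... Unused.
#' @return Tibble `model`, `genotype`, `term`, `estimate`.
#' @export
tidy.sm_fit <- function(x, ...) {
  J <- ncol(x$theta)
  tibble::tibble(
    model = x$model,
    genotype = rep(seq_len(J), each = 8),
    term = rep(theta_names, J),
    estimate = as.numeric(x$theta)
  )
}

#' Glance at a systems-mapping fit
#'
#' @param x An `sm_fit`.
#' @param ... Unused.
#' @return One-row tibble: `model`, `logLik`, `n`, `n_genotypes`,
#'   `sigma2_leaf`, `sigma2_stem`, `sigma2_root`, `lambda`, `n_starts_ok`.
#' @export
glance.sm_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model, logLik = x$loglik, n = x$n,
    n_genotypes = ncol(x$theta),
    sigma2_leaf = x$psi$sigma2[1], sigma2_stem = x$psi$sigma2[2],
    sigma2_root = x$psi$sigma2[3],
    lambda = x$coefs$lambda, n_starts_ok = x$n_starts_ok
  )
}

#' @export
print.sm_fit <- function(x, ...) {
  cat("Systems-mapping fit (", x$model, "), n = ", x$n,
      ", lnL = ", format(x$loglik, digits = 8), "\n", sep = "")
  est <- t(x$theta)
  rownames(est) <- paste("genotype", seq_len(nrow(est)))
  print(round(est, 3))
  cat("sigma^2 (leaf, stem, root): ",
      paste(format(x$psi$sigma2, digits = 4), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Table-style text report of point estimates (and optional bootstrap SEs)
#'
#' @param fit An `sm_fit`.
#' @param se Optional tibble from [bootstrap_se()].
#' @return A character vector of report lines (also printed).
#' @export
fit_report <- function(fit, se = NULL) {
  stopifnot(inherits(fit, "sm_fit"))
  J <- ncol(fit$theta)
  lines <- c(sprintf("Model %s  (lnL = %.4f)", fit$model, fit$loglik),
             paste(c("Genotype Est", sprintf("%8s", theta_names)),
                   collapse = " "))
  for (j in seq_len(J)) {
    lines <- c(lines, paste(c(sprintf("%8d PE ", j),
                              sprintf("%8.3f", fit$theta[, j])),
                            collapse = " "))
    if (!is.null(se)) {
      sej <- se$se[se$genotype == j]
      lines <- c(lines, paste(c("         SE ",
                                sprintf("%8.1e", sej)), collapse = " "))
    }
  }
  cat(lines, sep = "\n")
  invisible(lines)
}

#' Plot a genome-wide LR profile
#'
#' @param object An `sm_scan`.
#' @param threshold Optional LR threshold drawn as a dashed line.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sm_scan <- function(object, threshold = NULL, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$pos_cm, y = .data$lr)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$group),
                        scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "Position (cM)", y = "LR") +
    ggplot2::theme_bw()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = 2)
  }
  p
}

#' Plot a solved biomass trajectory
#'
#' @param object An `sm_trajectory` from [solve_trajectory()].
#' @param ... Unused.
#' @return A ggplot object with one line per organ plus whole-plant biomass.
#' @export
autoplot.sm_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(object, c("M_L", "M_S", "M_R", "W"),
                              names_to = "organ", values_to = "biomass")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$biomass,
                                     colour = .data$organ)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = c(M_L = "forestgreen",
                                            M_S = "steelblue",
                                            M_R = "tan4", W = "red")) +
    ggplot2::labs(x = "Time (days)", y = "Biomass (g)") +
    ggplot2::theme_bw()
}

#' Plot fitted genotype mean curves over the data
#'
#' @param object An `sm_fit`.
#' @param y Optional phenotype table overlaid as grey trajectories.
#' @param ... Unused.
#' @return A ggplot object faceted by organ.
#' @export
autoplot.sm_fit <- function(object, y = NULL, ...) {
  tg <- seq(min(object$times), max(object$times), length.out = 80)
  crv <- fitted_curves(object$coefs, tg) |>
    tidyr::pivot_longer(c("leaf", "stem", "root"),
                        names_to = "organ", values_to = "biomass")
  p <- ggplot2::ggplot(crv, ggplot2::aes(x = .data$time, y = .data$biomass))
  if (!is.null(y)) {
    yl <- trait_series(y) |>
      tidyr::pivot_longer(c("leaf", "stem", "root"),
                          names_to = "organ", values_to = "biomass")
    p <- p + ggplot2::geom_line(
      data = yl, ggplot2::aes(group = .data$ril),
      colour = "grey80", linewidth = 0.2)
  }
  p +
    ggplot2::geom_line(ggplot2::aes(colour = factor(.data$genotype)),
                       linewidth = 0.8) +
    ggplot2::facet_wrap(ggplot2::vars(.data$organ), scales = "free_y") +
    ggplot2::labs(x = "Time (days)", y = "Biomass (g)",
                  colour = "QTL genotype") +
    ggplot2::theme_bw()
}
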