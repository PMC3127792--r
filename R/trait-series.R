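#' Longitudinal three-organ phenotype records
#'
#' Validates a long-format table of biomass measurements: one row per RIL
#' per measurement time, columns `ril`, `time`, `leaf`, `stem`, `root`
#' (biomass in grams; time in the season unit). Time grids may be
#' ragged (progeny-specific numbers
#' of time points).
#'
#' @param df Data frame in the long dialect above.
#' @return A tibble of class `sm_pheno`, sorted by `ril` then `time`.
#' @export
trait_series <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("ril", "time", "leaf", "stem", "root")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("Phenotype table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  df <- tibble::as_tibble(df[need])
  df$ril <- as.character(df$ril)
  for (cn in c("time", "leaf", "stem", "root")) {
    if (!is.numeric(df[[cn]])) {
      stop("Column `", cn, "` must be numeric.", call. = FALSE)
    }
  }
  dup <- duplicated(df[c("ril", "time")])
  if (any(dup)) {
    stop("Duplicated (ril, time) row(s): ",
         paste(which(dup), collapse = ", "), call. = FALSE)
  }
  df <- dplyr::arrange(df, .data$ril, .data$time)
  class(df) <- c("sm_pheno", class(df))
  df
}

# Reshape a phenotype table into an (n x T x 3) array over the pooled time
# grid, NaN marking unobserved (ril, time) cells. Returns rils, times, Y.
#' @keywords internal
#' @noRd
pheno_arrays <- function(y) {
  y <- trait_series(y)
  rils <- unique(y$ril)
  times <- sort(unique(y$time))
  n <- length(rils); T <- length(times)
  Y <- array(NaN, dim = c(n, T, 3))
  i <- match(y$ril, rils)
  t <- match(y$time, times)
  Y[cbind(i, t, 1L)] <- y$leaf
  Y[cbind(i, t, 2L)] <- y$stem
  Y[cbind(i, t, 3L)] <- y$root
  list(rils = rils, times = times, Y = Y)
}

# Align a weight/probability matrix with the phenotype RIL ordering.
# Row names, when present, are authoritative; otherwise the caller must
# supply rows already in `rils` order.
#' @keywords internal
#' @noRd
align_weights <- function(weights, rils) {
  weights <- as.matrix(weights)
  if (!is.null(rownames(weights))) {
    if (!setequal(rownames(weights), rils)) {
      stop("Weight row names do not match the phenotype RIL ids.",
           call. = FALSE)
    }
    weights <- weights[rils, , drop = FALSE]
  } else if (nrow(weights) != length(rils)) {
    stop("Weights must have one row per RIL.", call. = FALSE)
  }
  weights
}

# Stack a list/matrix of per-genotype structural parameters into the 8 x J
# matrix used by the numerical core.
#' @keywords internal
#' @noRd
theta_matrix <- function(theta) {
  if (inherits(theta, "sm_ode_params")) theta <- list(theta)
  if (is.list(theta)) {
    theta <- vapply(theta, function(p) unlist(as_ode_params(p)[theta_names]),
                    numeric(8))
  }
  theta <- as.matrix(theta)
  stopifnot(nrow(theta) == 8)
  rownames(theta) <- theta_names
  theta
}
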