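#' Synthetic linkage map for a soybean-like RIL design
#'
#' Evenly spaced markers in equally sized linkage groups. The default
#' emulates the soybean design used throughout the package: 950 markers in
#' 25 groups (38 per group), each group spanning 100 cM.
#'
#' @param n_groups Number of linkage groups.
#' @param n_markers Total number of markers (distributed as evenly as
#'   possible across groups).
#' @param length_cm Span of each group in cM.
#' @return A [linkage_map()] tibble.
#' @export
sim_map <- function(n_groups = 25, n_markers = 950, length_cm = 100) {
  stopifnot(n_groups >= 1, n_markers >= 2 * n_groups, length_cm > 0)
  per <- diff(round(seq(0, n_markers, length.out = n_groups + 1)))
  purrr::map_dfr(seq_len(n_groups), function(g) {
    tibble::tibble(group = paste0("LG", g),
                   marker = sprintf("LG%d_m%d", g, seq_len(per[g])),
                   pos_cm = seq(0, length_cm, length.out = per[g]))
  }) |> linkage_map()
}

#' Simulate RIL genotypes along a linkage map
#'
#' Each RIL chromosome is a two-state Markov chain over the ordered markers
#' of each group: the first marker is parent-1 or parent-2 homozygous with
#' probability 1/2, and adjacent markers differ with the RIL-level
#' recombination fraction `R = 2r/(1+2r)` of their map distance. Groups are
#' independent; all loci are homozygous (fully inbred lines).
#'
#' @param map A [linkage_map()].
#' @param n Number of RILs.
#' @param generation Selfing generation (metadata; lines are treated as
#'   fully fixed, cf. [fixation_probability()]).
#' @param mapfun Map function for cM-to-r conversion.
#' @param seed Optional integer seed (uses the current RNG state if `NULL`).
#' @return A [genotype_matrix()] of `"A"`/`"B"` codes.
#' @export
simulate_ril_genomes <- function(map, n, generation = 7,
                                 mapfun = c("haldane", "kosambi"),
                                 seed = NULL) {
  map <- linkage_map(map)
  stopifnot(n >= 2, generation >= 2)
  if (!is.null(seed)) set.seed(seed)
  fn <- map_function(mapfun)
  geno <- matrix(NA_character_, n, nrow(map),
                 dimnames = list(sprintf("RIL%04d", seq_len(n)), map$marker))
  for (g in unique(map$group)) {
    idx <- which(map$group == g)
    Rs <- ril_expansion(fn(diff(map$pos_cm[idx])))
    state <- stats::rbinom(n, 1, 0.5)
    geno[, idx[1]] <- c("A", "B")[state + 1]
    for (m in seq_along(Rs)) {
      flip <- stats::rbinom(n, 1, Rs[m])
      state <- (state + flip) %% 2
      geno[, idx[m + 1]] <- c("A", "B")[state + 1]
    }
  }
  genotype_matrix(geno, map)
}

#' Reference generating parameter pair for the soybean-like design
#'
#' Two genotype-specific parameter sets for the biomass-partitioning system,
#' taken from the fitted two-genotype model at the second biomass QTL of the
#' soybean RIL study that this package's simulation design emulates.
#' Genotype 1 (parent-1 homozygote) carries the larger leaf allometric
#' constant.
#'
#' @return A list of two [ode_params()] objects.
#' @export
default_qtl_params <- function() {
  list(
    ode_params(alpha_L = 2.55, beta_L = 0.10, gamma_L = 0.31,
               alpha_S = 0.98, beta_S = 0.04,
               alpha_R = 1.11, beta_R = 0.51, gamma_R = 2.18),
    ode_params(alpha_L = 1.89, beta_L = 0.14, gamma_L = 0.44,
               alpha_S = 1.04, beta_S = 0.07,
               alpha_R = 1.11, beta_R = 0.56, gamma_R = 1.85)
  )
}

#' Residual variances from a target mid-season heritability
#'
#' At the middle measurement time `t*`, the genetic variance contributed by
#' an equal-frequency two-homozygote QTL is
#' \eqn{\sigma^2_{g,k} = \tfrac14 [\mu_{k,1}(t^*) - \mu_{k,2}(t^*)]^2};
#' the residual variance achieving per-trait heritability `h2` at `t*` is
#' \eqn{\sigma^2_k = \sigma^2_{g,k}(1 - h^2)/h^2}.
#'
#' @param params_pair List of two [ode_params()] (the generating genotypes).
#' @param times Measurement times (days).
#' @param h2 Target heritability per trait (scalar or length 3), in (0, 1).
#' @param t_star Calibration time; defaults to the middle measurement time
#'   `times[ceiling(length(times)/2)]`.
#' @return Length-3 vector of residual variances (g^2), with attribute
#'   `"sigma_g2"` (the genetic variances at `t_star`).
#' @export
heritability_to_sigma <- function(params_pair, times, h2, t_star = NULL) {
  stopifnot(length(params_pair) == 2)
  h2 <- rep_len(h2, 3)
  if (any(h2 <= 0) || any(h2 >= 1)) {
    stop("`h2` must lie strictly in (0, 1).", call. = FALSE)
  }
  if (is.null(t_star)) t_star <- times[ceiling(length(times) / 2)]
  mu1 <- solve_trajectory(params_pair[[1]], times)
  mu2 <- solve_trajectory(params_pair[[2]], times)
  i <- which(times == t_star)[1]
  d <- c(mu1$M_L[i] - mu2$M_L[i], mu1$M_S[i] - mu2$M_S[i],
         mu1$M_R[i] - mu2$M_R[i])
  if (any(d == 0)) {
    stop("Genotype means coincide at t* for at least one trait; the ",
         "heritability rescaling is undefined.", call. = FALSE)
  }
  sigma_g2 <- d^2 / 4
  out <- sigma_g2 * (1 - h2) / h2
  attr(out, "sigma_g2") <- sigma_g2
  out
}

#' Simulate phenotypes given genomes and a QTL
#'
#' Each RIL's QTL genotype is taken from its simulated chromosome when the
#' QTL coincides with a marker (drawn from the conditional probabilities
#' given the flanks when the marker is missing or the QTL lies between
#' markers); its phenotype is the genotype's ODE mean curve at the
#' measurement times plus independent Gaussian white noise per trait and
#' time.
#'
#' @param genomes Genotype matrix from [simulate_ril_genomes()].
#' @param map The linkage map.
#' @param qtl A [qtl_position()] row (or list with `group`, `pos_cm`).
#' @param params_pair List of two generating [ode_params()] (genotype 1 =
#'   parent-1 homozygote).
#' @param sigma Residual standard deviations per trait (length 3), or a
#'   variance vector from [heritability_to_sigma()] via `sqrt()`.
#' @param times Measurement times (season units).
#' @param time_jitter Half-width of a uniform per-RIL, per-occasion shift
#'   of the measurement times (0 = shared grid). Must be smaller than half
#'   the smallest gap so each line's times stay ordered.
#' @param dropout Probability that any single (RIL, occasion) record is
#'   missing completely at random.
#' @param seed Optional integer seed.
#' @return A list of class `sm_sim`: `pheno` ([trait_series()]), `geno`,
#'   `map`, and `truth` (QTL position, genotype assignment, generating
#'   parameters, noise SDs, times, seed).
#' @export
simulate_phenotypes <- function(genomes, map, qtl, params_pair, sigma,
                                times, time_jitter = 0, dropout = 0,
                                seed = NULL) {
  map <- linkage_map(map)
  genomes <- genotype_matrix(genomes, map)
  if (!all(c("d1", "d2", "left_idx") %in% names(qtl))) {
    qtl <- qtl_position(map, qtl$group, qtl$pos_cm)
  }
  sigma <- rep_len(as.numeric(sigma), 3)
  stopifnot(all(sigma >= 0), length(times) >= 2,
            time_jitter >= 0, dropout >= 0, dropout < 1)
  if (time_jitter >= min(diff(sort(times))) / 2) {
    stop("`time_jitter` must be below half the smallest time gap.",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(genomes)
  g <- integer(n)
  if (qtl$d1 == 0 || qtl$d2 == 0) {
    mk <- if (qtl$d1 == 0) qtl$left_idx else qtl$right_idx
    codes <- genomes[, mk]
    g[!is.na(codes)] <- ifelse(codes[!is.na(codes)] == "A", 1L, 2L)
  }
  todo <- which(g == 0L)
  if (length(todo) > 0) {
    om <- qtl_genotype_probs(genomes, map, qtl)
    g[todo] <- vapply(todo, function(i) {
      sample.int(2L, 1, prob = om[i, ])
    }, integer(1))
  }
  T <- length(times)
  t0 <- min(times)
  mu <- lapply(params_pair, solve_trajectory, times = times)
  pheno <- purrr::map_dfr(seq_len(n), function(i) {
    if (time_jitter > 0) {
      ti <- times + stats::runif(T, -time_jitter, time_jitter)
      ti[1] <- max(ti[1], t0)  # initial state is anchored at the season start
      m <- solve_trajectory(params_pair[[g[i]]], ti, t0 = t0)
    } else {
      ti <- times
      m <- mu[[g[i]]]
    }
    out <- tibble::tibble(
      ril = rownames(genomes)[i], time = ti,
      leaf = m$M_L + stats::rnorm(T, 0, sigma[1]),
      stem = m$M_S + stats::rnorm(T, 0, sigma[2]),
      root = m$M_R + stats::rnorm(T, 0, sigma[3])
    )
    if (dropout > 0) out <- out[stats::runif(T) >= dropout, ]
    out
  })
  structure(list(
    pheno = trait_series(pheno), geno = genomes, map = map,
    truth = list(qtl = qtl, genotype = g, params_pair = params_pair,
                 sigma = sigma, times = times, seed = seed)
  ), class = "sm_sim")
}

#' Simulate a complete soybean-like mapping dataset
#'
#' One-call generator reproducing the package's reference study conditions:
#' 184 RILs, a 25-group/950-marker map, one QTL at a marker, the reference
#' generating parameter pair, six measurement occasions concentrated on the
#' establishment phase where the organ dynamics are fast
#' (t = 2, 2.2, 2.5, 3, 4.5, 7 in the season time unit of roughly ten
#' days, i.e. days 20-70 after emergence), and white noise calibrated to a
#' per-trait heritability of 0.05 at the middle measurement time.
#'
#' @param n Number of RILs.
#' @param map Linkage map (default [sim_map()]).
#' @param qtl_group,qtl_pos_cm QTL location (defaults: first group, at the
#'   marker nearest the middle of the group).
#' @param params_pair Generating parameter pair (default
#'   [default_qtl_params()]); pass two identical sets (or `h2 = NULL` with
#'   explicit `sigma`) for a no-QTL null.
#' @param h2 Target mid-season heritability per trait; ignored when `sigma`
#'   is given.
#' @param sigma Optional explicit residual SDs (length 3).
#' @param times Measurement times (season time units).
#' @param time_jitter,dropout Passed to [simulate_phenotypes()]: per-RIL
#'   measurement-time jitter and MCAR record drop-out (both 0 by default).
#' @param generation Selfing generation of the RILs.
#' @param seed Integer seed (mandatory: the whole dataset is reproducible
#'   from it).
#' @return An `sm_sim` list (see [simulate_phenotypes()]).
#' @export
simulate_dataset <- function(n = 184, map = sim_map(),
                             qtl_group = NULL, qtl_pos_cm = NULL,
                             params_pair = default_qtl_params(),
                             h2 = 0.05, sigma = NULL,
                             times = c(2, 2.2, 2.5, 3, 4.5, 7),
                             time_jitter = 0, dropout = 0,
                             generation = 7, seed) {
  if (missing(seed)) stop("`seed` is mandatory.", call. = FALSE)
  map <- linkage_map(map)
  if (is.null(qtl_group)) qtl_group <- map$group[1]
  if (is.null(qtl_pos_cm)) {
    rows <- which(map$group == qtl_group)
    mid <- mean(range(map$pos_cm[rows]))
    qtl_pos_cm <- map$pos_cm[rows][which.min(abs(map$pos_cm[rows] - mid))]
  }
  if (is.null(sigma)) {
    if (is.null(h2)) stop("Give either `h2` or `sigma`.", call. = FALSE)
    sigma <- sqrt(heritability_to_sigma(params_pair, times, h2))
  }
  set.seed(seed)
  genomes <- simulate_ril_genomes(map, n, generation)
  qtl <- qtl_position(map, qtl_group, qtl_pos_cm)
  out <- simulate_phenotypes(genomes, map, qtl, params_pair, sigma, times,
                             time_jitter = time_jitter, dropout = dropout,
                             seed = NULL)
  out$truth$seed <- seed
  out
}
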