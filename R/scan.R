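#' Genome-wide likelihood-ratio scan for biomass-partitioning QTLs
#'
#' At every grid position the full two-genotype model ([fit_m1()]) is
#' compared against the position-independent single-curve null
#' ([fit_m0()], fitted once per dataset) by the LR statistic
#' `2(lnL1 - lnL0)`. Within each linkage group the structural estimates
#' warm-start the next position's fit; the first position of each group
#' uses the full multi-start.
#'
#' @param y Phenotypes ([trait_series()]).
#' @param geno Genotype matrix ([genotype_matrix()]); rows must match
#'   `unique(y$ril)`.
#' @param map Linkage map.
#' @param step Scan step in cM (marker positions are always included).
#' @param control [sm_control()] settings for the position fits.
#' @param mapfun Map function for the conditional genotype probabilities.
#' @param m0 Optional precomputed null fit (reused across permutations).
#' @param quiet Suppress per-position progress messages.
#' @return A tibble of class `sm_scan` with columns `group`, `pos_cm`, `lr`
#'   (NA where a position's fit failed) and attributes `m0` (the null fit),
#'   `step`, and optionally `threshold` once [permutation_threshold()] has
#'   been attached.
#' @export
genome_scan <- function(y, geno, map, step = 1, control = sm_control(),
                        mapfun = c("haldane", "kosambi"), m0 = NULL,
                        quiet = TRUE) {
  if (!inherits(y, "sm_fitdata")) y <- sm_fit_data(y)
  map <- linkage_map(map)
  geno <- genotype_matrix(geno, map)
  rils <- y$arr$rils
  if (nrow(geno) != length(rils)) {
    stop("Genotype matrix rows (", nrow(geno), ") do not match the ",
         length(rils), " RILs in the phenotypes.", call. = FALSE)
  }
  if (is.null(m0)) m0 <- fit_m0(y, control)
  null_start <- cbind(m0$theta, m0$theta)
  grid <- scan_grid(map, step)
  lr <- rep(NA_real_, nrow(grid))
  warm <- NULL
  cur_group <- NULL
  for (p in seq_len(nrow(grid))) {
    if (!identical(grid$group[p], cur_group)) {
      warm <- NULL
      cur_group <- grid$group[p]
    }
    pos <- qtl_position(map, grid$group[p], grid$pos_cm[p])
    om <- qtl_genotype_probs(geno, map, pos, mapfun)
    ctl <- control
    if (!is.null(warm)) {
      ctl$n_starts <- 1
      ctl$cycles <- max(1, ctl$cycles - 1)
    }
    fit <- try(fit_m1(y, om, ctl, theta_start = warm,
                      extra_starts = list(null_start),
                      sigma_start = m0$psi$sigma2), silent = TRUE)
    if (inherits(fit, "try-error")) {
      if (!quiet) message("Fit failed at ", pos$group, ":", pos$pos_cm)
      next
    }
    warm <- fit$theta
    lr[p] <- lr_statistic(fit, m0)
    if (!quiet) {
      message(sprintf("%s %6.1f cM  LR = %8.3f",
                      pos$group, pos$pos_cm, lr[p]))
    }
  }
  out <- tibble::tibble(group = grid$group, pos_cm = grid$pos_cm, lr = lr)
  class(out) <- c("sm_scan", class(out))
  attr(out, "m0") <- m0
  attr(out, "step") <- step
  out
}

#' Genome-wide permutation threshold for the LR scan
#'
#' Phenotype vectors are permuted against the genotype rows (breaking any
#' marker-trait association while preserving both marginals); the scan is
#' rerun on each permuted dataset and the genome-wide maximum LR recorded.
#' The threshold is the empirical `quantile` of these maxima. The null fit
#' is permutation-invariant and computed once.
#'
#' @inheritParams genome_scan
#' @param n_perm Number of permutations; must satisfy
#'   `n_perm * (1 - quantile) >= 5`.
#' @param quantile Genome-wide quantile (default 0.95).
#' @param seed Integer seed making the permutation set reproducible.
#' @return A list of class `sm_permnull`: `maxima`, `threshold`, `n_perm`,
#'   `quantile`, `seed`.
#' @export
permutation_threshold <- function(y, geno, map, n_perm = 1000,
                                  quantile = 0.95, seed, step = 1,
                                  control = sm_control(),
                                  mapfun = c("haldane", "kosambi")) {
  if (missing(seed)) stop("`seed` is mandatory.", call. = FALSE)
  if (n_perm * (1 - quantile) < 5 - 1e-9) {
    stop("`n_perm` = ", n_perm, " is too small for the ", quantile,
         " quantile (need n_perm * (1 - quantile) >= 5).", call. = FALSE)
  }
  if (!inherits(y, "sm_fitdata")) y <- sm_fit_data(y)
  map <- linkage_map(map)
  geno <- genotype_matrix(geno, map)
  m0 <- fit_m0(y, control)
  set.seed(seed)
  maxima <- vapply(seq_len(n_perm), function(b) {
    perm <- sample.int(nrow(geno))
    gp <- geno[perm, , drop = FALSE]
    rownames(gp) <- rownames(geno)  # re-key: rows now carry permuted genomes
    sc <- genome_scan(y, gp, map, step, control, mapfun, m0 = m0)
    max(sc$lr, na.rm = TRUE)
  }, numeric(1))
  structure(list(maxima = maxima,
                 threshold = as.numeric(stats::quantile(maxima, quantile)),
                 n_perm = n_perm, quantile = quantile, seed = seed),
            class = "sm_permnull")
}

#' Significant peaks of a scan
#'
#' @param scan An `sm_scan`.
#' @param threshold LR threshold (e.g. from [permutation_threshold()]).
#' @return Tibble of local per-group maxima exceeding the threshold.
#' @export
scan_peaks <- function(scan, threshold) {
  stopifnot(inherits(scan, "sm_scan"))
  scan |>
    dplyr::filter(!is.na(.data$lr)) |>
    dplyr::group_by(.data$group) |>
    dplyr::slice_max(.data$lr, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$lr >= threshold)
}

#' Power and false-positive study of the scan
#'
#' For each heritability level: simulate replicate datasets under the
#' two-genotype alternative and under the single-curve null, scan each at
#' the given step, and declare significance against a permutation threshold
#' estimated once per level from the first alternative replicate (a
#' shared-threshold approximation that keeps replicate studies tractable).
#' Power counts replicates whose peak exceeds the threshold within the true
#' QTL's linkage group and +/- 10 cM; the false-positive rate counts null
#' replicates declaring any significant position.
#'
#' @param params_pair Generating parameter pair (alternative).
#' @param h2_grid Heritability levels in (0, 1).
#' @param n_replicates Replicates per level (>= 20) for each of the
#'   alternative and null arms.
#' @param n Number of RILs per replicate.
#' @param map Linkage map (default: a single 50-cM group of 6 markers, the
#'   package's reduced study design).
#' @param qtl_group,qtl_pos_cm True QTL location (defaults to the middle
#'   marker of the first group).
#' @param times Measurement times.
#' @param n_perm,quantile Permutation settings for the shared threshold.
#' @param step Scan step (cM). The default matches the reduced map's
#'   marker spacing, i.e. the replicate studies scan marker positions:
#'   at a RIL marker the conditional genotype probabilities are hard 0/1,
#'   so the mixture cannot inflate the LR by re-discovering phenotypic
#'   heterogeneity unlinked to the locus, which keeps replicate scans both
#'   calibrated and fast. Pass a smaller step to scan within intervals.
#' @param window_cm Localization window for crediting power.
#' @param control [sm_control()] for all fits.
#' @param seed Integer seed.
#' @return Tibble of class `sm_power`: `h2`, `power`, `fpr`, `threshold`,
#'   `n_replicates`, with attribute `"details"` holding per-replicate peak
#'   records.
#' @export
power_study <- function(params_pair = default_qtl_params(),
                        h2_grid = 0.05, n_replicates = 50, n = 184,
                        map = sim_map(n_groups = 1, n_markers = 6,
                                      length_cm = 50),
                        qtl_group = NULL, qtl_pos_cm = NULL,
                        times = c(2, 2.2, 2.5, 3, 4.5, 7),
                        n_perm = 100, quantile = 0.95, step = 10,
                        window_cm = 10, control = sm_control(), seed) {
  if (missing(seed)) stop("`seed` is mandatory.", call. = FALSE)
  stopifnot(n_replicates >= 20, all(h2_grid > 0), all(h2_grid < 1))
  map <- linkage_map(map)
  if (is.null(qtl_group)) qtl_group <- map$group[1]
  if (is.null(qtl_pos_cm)) {
    rows <- which(map$group == qtl_group)
    mid <- mean(range(map$pos_cm[rows]))
    qtl_pos_cm <- map$pos_cm[rows][which.min(abs(map$pos_cm[rows] - mid))]
  }
  null_pair <- list(params_pair[[1]], params_pair[[1]])
  details <- list()
  res <- purrr::map_dfr(seq_along(h2_grid), function(hi) {
    h2 <- h2_grid[hi]
    sigma <- sqrt(heritability_to_sigma(params_pair, times, h2))
    base_seed <- seed + 1000L * (hi - 1L)
    first <- simulate_dataset(n = n, map = map, qtl_group = qtl_group,
                              qtl_pos_cm = qtl_pos_cm,
                              params_pair = params_pair, sigma = sigma,
                              times = times, seed = base_seed)
    thr <- permutation_threshold(first$pheno, first$geno, map,
                                 n_perm = n_perm, quantile = quantile,
                                 seed = base_seed + 1L, step = step,
                                 control = control)$threshold
    hit <- logical(n_replicates)
    fp <- logical(n_replicates)
    for (r in seq_len(n_replicates)) {
      alt <- if (r == 1) first else
        simulate_dataset(n = n, map = map, qtl_group = qtl_group,
                         qtl_pos_cm = qtl_pos_cm,
                         params_pair = params_pair, sigma = sigma,
                         times = times, seed = base_seed + 2L * r)
      sc <- genome_scan(alt$pheno, alt$geno, map, step, control)
      pk <- sc[which.max(sc$lr), ]
      hit[r] <- nrow(pk) == 1 && pk$lr >= thr && pk$group == qtl_group &&
        abs(pk$pos_cm - qtl_pos_cm) <= window_cm
      nul <- simulate_dataset(n = n, map = map, qtl_group = qtl_group,
                              qtl_pos_cm = qtl_pos_cm,
                              params_pair = null_pair, sigma = sigma,
                              times = times, seed = base_seed + 2L * r + 1L)
      scn <- genome_scan(nul$pheno, nul$geno, map, step, control)
      fp[r] <- max(scn$lr, na.rm = TRUE) >= thr
      details[[length(details) + 1]] <<- tibble::tibble(
        h2 = h2, replicate = r, peak_lr = pk$lr, peak_pos = pk$pos_cm,
        null_max_lr = max(scn$lr, na.rm = TRUE))
    }
    tibble::tibble(h2 = h2, power = mean(hit), fpr = mean(fp),
                   threshold = thr, n_replicates = n_replicates)
  })
  class(res) <- c("sm_power", class(res))
  attr(res, "details") <- dplyr::bind_rows(details)
  res
}
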