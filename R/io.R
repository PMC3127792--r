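#' Read and write the package's delimited-text dialects
#'
#' Linkage map: CSV `group,marker,position_cM`. Genotypes: CSV with a `ril`
#' identifier column followed by one column per marker in map order, codes
#' `A` / `B` / `-`. Phenotypes: long CSV `ril,time,leaf,stem,root` (grams;
#' ragged time grids allowed).
#'
#' @param path File path.
#' @return `read_linkage_map()`: an [linkage_map()] tibble.
#' @name sm_io
NULL

#' @rdname sm_io
#' @export
read_linkage_map <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df)[names(df) == "position_cM"] <- "pos_cm"
  linkage_map(df)
}

#' @rdname sm_io
#' @param map A linkage map.
#' @export
write_linkage_map <- function(map, path) {
  map <- linkage_map(map)
  out <- data.frame(group = map$group, marker = map$marker,
                    position_cM = map$pos_cm)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname sm_io
#' @param geno A genotype matrix.
#' @export
write_genotypes <- function(geno, path) {
  df <- data.frame(ril = rownames(geno), geno, check.names = FALSE)
  df[is.na(df)] <- "-"
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname sm_io
#' @export
read_genotypes <- function(path, map) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        colClasses = "character")
  if (names(df)[1] != "ril") {
    stop("Genotype CSV must start with a `ril` column.", call. = FALSE)
  }
  geno <- as.matrix(df[, -1, drop = FALSE])
  rownames(geno) <- df$ril
  genotype_matrix(geno, map)
}

#' @rdname sm_io
#' @details `read_genotypes_rotated()` reads the rotated dialect common in
#'   mapping software: rows are markers (columns `group`, `marker`,
#'   `position_cM`, then one column per RIL).
#' @export
read_genotypes_rotated <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        colClasses = "character")
  need <- c("group", "marker", "position_cM")
  if (!all(need %in% names(df))) {
    stop("Rotated genotype CSV needs columns group, marker, position_cM.",
         call. = FALSE)
  }
  map <- linkage_map(data.frame(group = df$group, marker = df$marker,
                                pos_cm = as.numeric(df$position_cM)))
  rils <- setdiff(names(df), need)
  geno <- t(as.matrix(df[, rils, drop = FALSE]))
  colnames(geno) <- df$marker
  list(map = map, geno = genotype_matrix(geno, map))
}

#' Read a longitudinal phenotype file
#'
#' Long CSV `ril,time,leaf,stem,root`. Validation errors name the offending
#' file rows (1-based, excluding the header).
#'
#' @param path File path.
#' @param rils Optional vector of known RIL identifiers; unknown ids error.
#' @param allow_negative Accept negative biomass values (white measurement
#'   noise on small organs can push simulated records below zero; field
#'   data should keep the default `FALSE`).
#' @return A [trait_series()] tibble.
#' @export
read_phenotypes <- function(path, rils = NULL, allow_negative = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("ril", "time", "leaf", "stem", "root")
  if (!all(need %in% names(df))) {
    stop("Phenotype CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  for (cn in c("time", "leaf", "stem", "root")) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    bad <- which(is.na(v) & !is.na(df[[cn]]))
    if (length(bad) > 0) {
      stop("Non-numeric `", cn, "` in row(s): ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
    df[[cn]] <- v
  }
  neg <- which(df$leaf < 0 | df$stem < 0 | df$root < 0)
  if (allow_negative) neg <- integer(0)
  if (length(neg) > 0) {
    stop("Negative biomass in row(s): ",
         paste(utils::head(neg, 5), collapse = ", "), call. = FALSE)
  }
  dup <- which(duplicated(df[c("ril", "time")]))
  if (length(dup) > 0) {
    stop("Duplicated (ril, time) in row(s): ",
         paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  }
  if (!is.null(rils)) {
    unk <- which(!(df$ril %in% rils))
    if (length(unk) > 0) {
      stop("Unknown ril id in row(s): ",
           paste(utils::head(unk, 5), collapse = ", "), call. = FALSE)
    }
  }
  trait_series(df)
}

#' @rdname read_phenotypes
#' @param y A [trait_series()] table.
#' @export
write_phenotypes <- function(y, path) {
  y <- trait_series(y)
  utils::write.csv(as.data.frame(y), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a scan profile as TSV (`group<TAB>position_cM<TAB>LR`)
#'
#' @param scan An `sm_scan`.
#' @param path Output TSV path.
#' @param sidecar Optional JSON path receiving threshold/peak metadata.
#' @param threshold Optional LR threshold recorded in the sidecar.
#' @export
write_scan <- function(scan, path, sidecar = NULL, threshold = NULL) {
  stopifnot(inherits(scan, "sm_scan"))
  out <- data.frame(group = scan$group, position_cM = scan$pos_cm,
                    LR = scan$lr)
  utils::write.table(out, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  if (!is.null(sidecar)) {
    meta <- list(step_cm = attr(scan, "step"), threshold = threshold)
    if (!is.null(threshold)) {
      pk <- scan_peaks(scan, threshold)
      meta$peaks <- as.data.frame(pk)
    }
    jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' Serialize a fit to JSON
#'
#' Parameters, variances, log-likelihood, model tag and convergence
#' diagnostics, round-trippable for reproducibility records.
#'
#' @param fit An `sm_fit`.
#' @param path JSON output path.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "sm_fit"))
  obj <- list(
    model = fit$model,
    loglik = fit$loglik,
    n = fit$n,
    theta = lapply(seq_len(ncol(fit$theta)), function(j) {
      as.list(stats::setNames(fit$theta[, j], theta_names))
    }),
    sigma2 = fit$psi$sigma2,
    lambda = fit$coefs$lambda,
    start_logliks = fit$start_logliks
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Export a trajectory as tidy CSV (`genotype,time,M_L,M_S,M_R,W`)
#'
#' @param trajs Named list of [solve_trajectory()] tibbles (names =
#'   genotype labels), or a single trajectory.
#' @param path Output CSV path.
#' @export
write_trajectories <- function(trajs, path) {
  if (inherits(trajs, "sm_trajectory")) trajs <- list(`1` = trajs)
  out <- purrr::imap_dfr(trajs, function(tr, nm) {
    tibble::tibble(genotype = nm, time = tr$time, M_L = tr$M_L,
                   M_S = tr$M_S, M_R = tr$M_R, W = tr$W)
  })
  utils::write.csv(as.data.frame(out), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
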