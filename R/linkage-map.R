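#' Construct and validate a linkage map
#'
#' A linkage map is a tibble with columns `group` (linkage group identifier),
#' `marker` (name, unique genome-wide) and `pos_cm` (position in cM,
#' non-negative and strictly increasing within each group). Groups intended
#' for QTL scanning must carry at least two markers.
#'
#' @param map A data frame with columns `group`, `marker`, `pos_cm`.
#' @return A validated tibble of class `sm_map`.
#' @examples
#' linkage_map(data.frame(group = "LG1", marker = c("m1", "m2"),
#'                        pos_cm = c(0, 12.5)))
#' @export
linkage_map <- function(map) {
  stopifnot(is.data.frame(map))
  need <- c("group", "marker", "pos_cm")
  miss <- setdiff(need, names(map))
  if (length(miss) > 0) {
    stop("Map is missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  map <- tibble::as_tibble(map[need])
  map$marker <- as.character(map$marker)
  map$pos_cm <- as.numeric(map$pos_cm)
  if (anyDuplicated(map$marker)) {
    stop("Marker names must be unique genome-wide.", call. = FALSE)
  }
  if (any(!is.finite(map$pos_cm)) || any(map$pos_cm < 0)) {
    stop("Positions must be finite and non-negative.", call. = FALSE)
  }
  ok <- map |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(incr = all(diff(.data$pos_cm) > 0), .groups = "drop")
  if (!all(ok$incr)) {
    bad <- ok$group[!ok$incr]
    stop("Positions must be strictly increasing within group(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  class(map) <- c("sm_map", class(map))
  map
}

#' Validate a RIL genotype matrix against a linkage map
#'
#' Genotypes are coded `"A"` (parent-1 homozygote), `"B"` (parent-2
#' homozygote) or `NA` (missing). Columns must match the map's marker order.
#'
#' @param geno A character matrix (RILs x markers) using codes
#'   `"A"`, `"B"`, `"-"`/`NA`.
#' @param map A linkage map from [linkage_map()].
#' @return The genotype matrix with `"-"` recoded to `NA`.
#' @export
genotype_matrix <- function(geno, map) {
  geno <- as.matrix(geno)
  map <- linkage_map(map)
  if (ncol(geno) != nrow(map)) {
    stop("Genotype matrix has ", ncol(geno), " columns but the map has ",
         nrow(map), " markers.", call. = FALSE)
  }
  if (!is.null(colnames(geno)) && !identical(colnames(geno), map$marker)) {
    stop("Genotype column names do not match the map's marker order.",
         call. = FALSE)
  }
  geno[geno == "-"] <- NA_character_
  bad <- !is.na(geno) & !(geno %in% c("A", "B"))
  if (any(bad)) {
    stop("Unknown genotype code(s): ",
         paste(unique(geno[bad]), collapse = ", "),
         " (expected \"A\", \"B\", \"-\"/NA).", call. = FALSE)
  }
  colnames(geno) <- map$marker
  if (is.null(rownames(geno))) rownames(geno) <- paste0("RIL", seq_len(nrow(geno)))
  geno
}

#' Locate a genome position within its marker interval
#'
#' Resolves a (group, cM) coordinate to its flanking markers and the
#' distances `d1`, `d2` (cM) to the left and right flank. Positions
#' coincident with a marker return that marker as the left flank with
#' `d1 = 0`.
#'
#' @param map A linkage map.
#' @param group Linkage group identifier.
#' @param pos_cm Position in cM; must lie within the group's marker span.
#' @return A one-row tibble: `group`, `pos_cm`, `left`, `right` (marker
#'   names), `left_idx`, `right_idx` (row indices into the map), `d1`, `d2`.
#' @export
qtl_position <- function(map, group, pos_cm) {
  map <- linkage_map(map)
  rows <- which(map$group == group)
  if (length(rows) < 2) {
    stop("Group ", group, " is absent or has fewer than 2 markers.", call. = FALSE)
  }
  pos <- map$pos_cm[rows]
  if (pos_cm < pos[1] || pos_cm > pos[length(pos)]) {
    stop(sprintf("Position %.3f cM lies outside group %s (span %.3f-%.3f cM).",
                 pos_cm, group, pos[1], pos[length(pos)]), call. = FALSE)
  }
  i <- findInterval(pos_cm, pos, rightmost.closed = TRUE)
  left_idx <- rows[i]
  right_idx <- rows[min(i + 1, length(rows))]
  if (right_idx == left_idx) right_idx <- rows[i - 1 + 1]  # pos at last marker
  if (pos_cm == pos[length(pos)]) {
    left_idx <- rows[length(rows) - 1]
    right_idx <- rows[length(rows)]
  }
  tibble::tibble(
    group = group, pos_cm = pos_cm,
    left = map$marker[left_idx], right = map$marker[right_idx],
    left_idx = left_idx, right_idx = right_idx,
    d1 = pos_cm - map$pos_cm[left_idx],
    d2 = map$pos_cm[right_idx] - pos_cm
  )
}

#' Scan grid over a linkage map
#'
#' Positions every `step` cM along each group, always including marker
#' positions, as used by [genome_scan()].
#'
#' @param map A linkage map.
#' @param step Grid step in cM.
#' @return Tibble with columns `group`, `pos_cm`.
#' @export
scan_grid <- function(map, step = 1) {
  map <- linkage_map(map)
  stopifnot(step > 0)
  map |>
    dplyr::group_by(.data$group) |>
    dplyr::reframe(pos_cm = sort(unique(c(
      seq(min(.data$pos_cm), max(.data$pos_cm), by = step), .data$pos_cm
    ))))
}
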