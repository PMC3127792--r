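#' Map functions: genetic distance to recombination fraction
#'
#' Convert a genetic distance in centiMorgans into a recombination fraction
#' per meiosis. `haldane_cm_to_r()` assumes no crossover interference,
#' `kosambi_cm_to_r()` allows for positive interference. Both are vectorised.
#'
#' @param d Genetic distance in cM (non-negative, possibly vector).
#' @return Recombination fraction(s) in `[0, 0.5)`.
#' @examples
#' haldane_cm_to_r(10)   # 0.0906
#' kosambi_cm_to_r(10)   # 0.0987
#' @export
haldane_cm_to_r <- function(d) {
  check_nonneg(d, "d")
  0.5 * (1 - exp(-2 * d / 100))
}

#' @rdname haldane_cm_to_r
#' @export
kosambi_cm_to_r <- function(d) {
  check_nonneg(d, "d")
  0.5 * tanh(2 * d / 100)
}

#' Recombination fraction between loci in a selfed RIL population
#'
#' In recombinant inbred lines derived by repeated selfing, recombinant
#' haplotypes accumulate over generations, so the observed fraction of
#' recombinant lines between two loci exceeds the per-meiosis recombination
#' fraction. For fully inbred selfed RILs the expansion is
#' `R = 2r / (1 + 2r)` (Haldane-Waddington).
#'
#' @param r Per-meiosis recombination fraction(s) in `[0, 0.5]`.
#' @return RIL-level recombination fraction(s) `R` in `[0, 0.5]`.
#' @export
ril_expansion <- function(r) {
  if (any(!is.finite(r)) || any(r < 0) || any(r > 0.5)) {
    stop("`r` must lie in [0, 0.5].", call. = FALSE)
  }
  2 * r / (1 + 2 * r)
}

#' Probability of fixation at a locus after repeated selfing
#'
#' After `generation` generations of selfing starting from the F1, the
#' probability that a given locus is homozygous is `1 - 0.5^(generation - 1)`;
#' by the F7 this is about 0.984, which is why RILs past the F7 are treated
#' as fully homozygous.
#'
#' @param generation Selfing generation (integer >= 2; F2 corresponds to 2).
#' @return Fixation probability.
#' @export
fixation_probability <- function(generation) {
  if (any(generation < 2) || any(generation != round(generation))) {
    stop("`generation` must be an integer >= 2.", call. = FALSE)
  }
  1 - 0.5^(generation - 1)
}

#' @keywords internal
#' @noRd
check_nonneg <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0)) {
    stop(sprintf("`%s` must be finite and non-negative.", name), call. = FALSE)
  }
  invisible(x)
}

#' @keywords internal
#' @noRd
map_function <- function(mapfun = c("haldane", "kosambi")) {
  mapfun <- match.arg(mapfun)
  if (mapfun == "haldane") haldane_cm_to_r else kosambi_cm_to_r
}
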