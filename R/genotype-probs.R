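#' Conditional QTL genotype probabilities in a RIL population
#'
#' For a putative QTL at a given position, computes for every RIL the
#' conditional probability of carrying each of the two homozygous QTL
#' genotypes given its flanking-marker genotypes. Along a RIL chromosome the
#' genotype sequence is modelled as a Markov chain in which adjacent loci
#' differ with the RIL-level recombination fraction `R = 2r/(1+2r)`
#' (no crossover interference within the interval). Missing flanks are
#' handled by conditioning on the informative flank only; when both flanks
#' are missing the prior (1/2, 1/2) is returned. Markers beyond the flanking
#' pair carry no additional information under the Markov model and are not
#' used.
#'
#' @param geno Genotype matrix from [genotype_matrix()].
#' @param map Linkage map from [linkage_map()].
#' @param pos A position as returned by [qtl_position()], or a list/row with
#'   `group` and `pos_cm`.
#' @param mapfun Map function: `"haldane"` (default) or `"kosambi"`.
#' @return An `n x 2` matrix of probabilities with columns `A` and `B`
#'   (parent-1 and parent-2 homozygote); rows sum to 1.
#' @examples
#' map <- linkage_map(data.frame(group = 1, marker = c("m1", "m2"),
#'                               pos_cm = c(0, 20)))
#' g <- genotype_matrix(rbind(c("A", "A"), c("A", "B"), c("-", "-")), map)
#' qtl_genotype_probs(g, map, qtl_position(map, 1, 10))
#' @export
qtl_genotype_probs <- function(geno, map, pos, mapfun = c("haldane", "kosambi")) {
  map <- linkage_map(map)
  geno <- genotype_matrix(geno, map)
  if (!all(c("left_idx", "right_idx", "d1", "d2") %in% names(pos))) {
    pos <- qtl_position(map, pos$group, pos$pos_cm)
  }
  fn <- map_function(mapfun)
  R1 <- ril_expansion(fn(pos$d1))
  R2 <- ril_expansion(fn(pos$d2))
  g1 <- geno[, pos$left_idx]
  g2 <- geno[, pos$right_idx]

  # transition weight toward QTL genotype "A"
  t_to_A <- function(g, R) ifelse(is.na(g), 1, ifelse(g == "A", 1 - R, R))
  t_to_B <- function(g, R) ifelse(is.na(g), 1, ifelse(g == "B", 1 - R, R))
  wA <- t_to_A(g1, R1) * t_to_A(g2, R2)
  wB <- t_to_B(g1, R1) * t_to_B(g2, R2)
  omega <- cbind(A = wA / (wA + wB), B = wB / (wA + wB))
  rownames(omega) <- rownames(geno)
  omega
}
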