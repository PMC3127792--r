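# Shared fixtures, built in code.

toy_map <- function(spacing = 10, n_mark = 6, group = "LG1") {
  linkage_map(data.frame(group = group,
                         marker = paste0(group, "_m", seq_len(n_mark)),
                         pos_cm = spacing * (seq_len(n_mark) - 1)))
}

# deterministic two-genotype phenotype set on exact ODE curves
ode_pheno <- function(n_per = 5, times = c(2, 2.2, 2.5, 3, 4.5, 7),
                      params = default_qtl_params(), sigma = 0,
                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- 2 * n_per
  g <- rep(1:2, each = n_per)
  mu <- lapply(params, solve_trajectory, times = times)
  pheno <- purrr::map_dfr(seq_len(n), function(i) {
    m <- mu[[g[i]]]
    tibble::tibble(ril = sprintf("R%03d", i), time = times,
                   leaf = m$M_L + stats::rnorm(length(times), 0, sigma),
                   stem = m$M_S + stats::rnorm(length(times), 0, sigma),
                   root = m$M_R + stats::rnorm(length(times), 0, sigma))
  })
  omega <- cbind(as.numeric(g == 1), as.numeric(g == 2))
  rownames(omega) <- sprintf("R%03d", seq_len(n))
  list(pheno = trait_series(pheno), omega = omega, genotype = g, mu = mu)
}

# independent enumeration oracle for conditional QTL genotype probabilities:
# joint probability table of (left flank, QTL, right flank) from the
# two-state Markov chain with RIL-level recombination fractions, then
# conditioning by summation.
enum_qtl_probs <- function(g1, g2, R1, R2) {
  states <- c("A", "B")
  joint <- matrix(0, 2, dimnames = list(states, NULL))
  pq <- c(A = 0, B = 0)
  for (m1 in states) for (q in states) for (m2 in states) {
    p <- 0.5 *
      (if (m1 == q) 1 - R1 else R1) *
      (if (q == m2) 1 - R2 else R2)
    keep <- (is.na(g1) || m1 == g1) && (is.na(g2) || m2 == g2)
    if (keep) pq[q] <- pq[q] + p
  }
  pq / sum(pq)
}
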