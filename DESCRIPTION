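Package: sysmapr
Title: Systems Mapping of Dynamic Traits via ODE-Constrained QTL Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative trait locus (QTL) interval mapping for recombinant
    inbred line (RIL) populations in which each QTL genotype's mean phenotype
    is the solution of a coupled allometric system of ordinary differential
    equations for leaf, stem and root biomass. Genotype-specific mean curves
    are estimated inside a mixture likelihood by penalized B-spline parameter
    cascading (generalized profiling). Includes linkage-map arithmetic and
    conditional QTL genotype probabilities, genome-wide likelihood-ratio
    scans with permutation thresholds, parametric-bootstrap standard errors,
    and a synthetic-data generator emulating a soybean RIL design for power,
    false-positive and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    rlang,
    splines,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
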