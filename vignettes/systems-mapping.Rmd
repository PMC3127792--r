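---
title: "Systems mapping: ODE-constrained QTL models for biomass partitioning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Systems mapping: ODE-constrained QTL models for biomass partitioning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sysmapr)
```

## The model

`sysmapr` maps quantitative trait loci (QTLs) whose effect is expressed not
on a single measurement but on the *dynamics* of biomass partitioning. The
phenotype of a recombinant inbred line (RIL) is a season-long trajectory of
leaf, stem and root dry mass, and a QTL genotype is characterised by the
parameters of a coupled allometric system,

$$
\frac{dM_L}{dt} = \alpha_L W^{\beta_L} - \gamma_L M_L,\qquad
\frac{dM_S}{dt} = \alpha_S W^{\beta_S},\qquad
\frac{dM_R}{dt} = \alpha_R W^{\beta_R} - \gamma_R M_R,
$$

with whole-plant biomass $W = M_L + M_S + M_R$. Each organ acquires new
biomass at a rate scaling allometrically with whole-plant size
($\alpha_k$, the allometric constant in $\mathrm{g}^{1-\beta_k}$ per unit
time; $\beta_k$, the dimensionless scaling exponent), and leaves and roots
additionally lose ageing tissue at first-order rates $\gamma_L$,
$\gamma_R$ (per unit time); the stem does not senesce. Under typical
parameter values the leaf and root pools chase a quasi-equilibrium
$(\alpha_k/\gamma_k) W^{\beta_k}$ that itself rises as the plant grows,
producing decelerating — but not declining — organ curves, while the stem
accumulates monotonically and takes an increasing share of the whole-plant
biomass. Declining organ curves arise in this system only when a pool
starts *above* its quasi-equilibrium, which is how the model expresses
senescence-driven loss.

Initial organ masses at the first measurement occasion are treated as three
auxiliary positive quantities per genotype. In the spline representation
below they never appear explicitly — the fitted curve's value at the season
start plays that role — but `solve_trajectory()` and the simulator require
them, and fits report them as the fitted curve evaluated at the first
occasion.

### Time units

All rate constants are expressed per *season time unit*, with the default
study design placing six measurement occasions at
$t = 2, 2.2, 2.5, 3, 4.5, 7$. One unit corresponds to roughly ten days of
the emulated field protocol (first sampling twenty days after seedling
emergence, then repeated measurements at five-to-ten-day intervals), so the
default grid spans about days 20–70. This scaling was chosen by a design
analysis rather than convention: with the reference parameter values, the
organ time constants $1/\gamma_k$ range from half a unit (roots) to three
units (leaves). A grid that samples only every two or more units contains
essentially no information about the elimination rates — the transients
complete between observations, and the expected estimator standard
deviations computed from the mean-curve Fisher information explode by
orders of magnitude. The default grid concentrates occasions where the
modelled dynamics are fast; section *Identifiability* quantifies what it
can and cannot determine.

## The mixture likelihood

In a selfed RIL population each line is homozygous, so a QTL segregates two
genotype classes. The QTL genotype of line $i$ is unobserved; its
conditional probability $\omega_{j|i}$ given the flanking-marker genotypes
follows from modelling the chromosome as a two-state Markov chain along the
ordered loci, with adjacent loci differing with the RIL-level recombination
fraction $R = 2r/(1+2r)$ (Haldane–Waddington inflation of the per-meiosis
fraction $r$; no crossover interference within an interval; missing flanks
conditioned out; both flanks missing gives the $1/2, 1/2$ prior). The data
likelihood is the genotype mixture

$$
L(\Theta, \Psi) \;=\; \prod_{i=1}^n \sum_{j=1}^2 \omega_{j|i}\,
f_j(\mathbf z_i;\, \Theta_j, \Psi),
$$

where $\mathbf z_i$ stacks line $i$'s leaf, stem and root measurements
(time grids may be progeny-specific) and $f_j$ is multivariate normal about
genotype $j$'s mean curves. $\Psi$ is diagonal with trait-specific,
time-constant variances — matching white measurement noise — with an
optional per-trait AR(1) correlation in `mixture_loglik()`; cross-trait
residual covariance is fixed at zero, a stated limitation. Genotype labels
are anchored to parental marker phase (genotype 1 carries the parent-1
allele), which removes label switching.

## Parameter cascading

The mean curves solve a nonlinear ODE system with no closed form, so each
genotype–trait curve is represented as a cubic B-spline,
$\mu_{kj}(t) = \phi(t)^\top c_{kj}$, and the coefficients are estimated at
the *inner* level by minimising

$$
U(c \mid \Theta) = \sum_{k,j,i} \omega_{j|i}
  \sum_t \frac{[y_{ki}(t) - \mu_{kj}(t)]^2}{\sigma_k^2}
  + \lambda \sum_{k,j} \int \Big[\frac{d\mu_{kj}}{dt}
  - f_k(\mu_j(t); \Theta_j)\Big]^2 dt ,
$$

the second term an ODE-fidelity penalty evaluated by Gauss–Legendre
quadrature (five nodes per knot span). Because the weighted data term
collapses to per-time weighted means, the inner problem separates by
genotype into small damped Gauss–Newton solves, which the package
implements in compiled code. At the *outer* level the structural
parameters $\Theta$ maximise the mixture log-likelihood with
$c = \hat c(\Theta)$ profiled out (parameter cascading, equivalently
generalized profiling). The outer gradient uses the implicit-function
theorem: $d\hat c/d\Theta = -H^{-1} U_{c\Theta}$ with the exact inner
Hessian $H$, giving an analytic profile gradient that a unit test verifies
against central finite differences. Residual variances are profiled by
EM-style updates between optimisation cycles (posterior-weighted residual
sums of squares over observation counts).

Numerical choices that matter:

* **Knots.** Knots are placed at every observed measurement time and each
  inter-observation span is subdivided so no span exceeds 1/20 of the
  season (`refine_interior()`). The subdivision is what lets the spline
  space contain the ODE solutions when the dynamics are faster than the
  sampling interval; without it the penalty systematically distorts the
  fitted curves and biases $\Theta$.
* **Penalty weight.** Default $\lambda = 100$, chosen by the standard
  stabilisation rule: sweep $\lambda$ upward and report estimates at the
  value where they stop changing. On the reference conditions the default
  sits in the stable range; far larger values push the inner problem into
  the near-interpolating regime, where the spline-approximation floor and
  the elimination-rate ridge interact and estimates destabilise. The
  equivalence test against a direct ODE-solve fit uses $\lambda = 10^3$
  on a finer basis for exactly this reason. `sm_control(lambda = )`
  overrides the default.
* **Outer optimisation.** BFGS on log-transformed positive parameters
  (log $\alpha$, log $\gamma$; $\beta$ untransformed, clamped to
  $[-3, 3]$) with the analytic gradient, optionally preceded by a
  Nelder–Mead stage. Multi-start design: gradient-matching values (organ
  production/loss terms regressed on powers of smoothed $W$ from a
  ridge-smoothed fit of the weighted mean curves), the same values with
  elimination rates scaled by $5^{\pm 1}$ — covering the fast/slow
  equilibration ridge described below — a collapsed equal-genotype start,
  and log-normal jitters. The best final log-likelihood wins.
* **Degenerate inputs.** Whole-plant biomass is floored at $10^{-8}$ g
  inside the penalty (powers of non-positive numbers are undefined);
  non-finite warm starts are reset; singular inner Hessians fall back to a
  ridge-stabilised solve; small negative LR values (optimizer tolerance)
  are clamped to zero with a warning, and every scan fit includes the
  null-fit start so the full model cannot converge below its nested
  submodel.

## Scans, thresholds, and error rates

`genome_scan()` computes, every `step` cM (markers always included), the
likelihood-ratio statistic $\mathrm{LR} = 2(\ln L_1 - \ln L_0)$ between the
two-genotype model and the position-independent single-curve null (fitted
once per dataset). Structural estimates warm-start the next position.
Significance uses `permutation_threshold()`: phenotype vectors are permuted
against genotype rows, the genome-wide maximum LR recorded per permutation,
and the threshold taken as the empirical 95th percentile (1000 permutations
by default; the null fit is permutation-invariant and reused).
`power_study()` wraps the whole loop: per heritability level it simulates
alternative and no-QTL replicates, estimates one shared threshold from
permutations of the first alternative replicate (a documented
approximation that keeps replicate studies tractable), and reports power —
a significant peak within the true linkage group and ±10 cM — and the
false-positive rate on the null arm.

One behaviour of the genotype-mixture likelihood deserves emphasis. At
positions *between* markers the conditional genotype probabilities leave
the mixture real freedom, and the fitted two-component model can then
gain enormously (hundreds to thousands of log-units when residual
variances are small) by re-discovering genuine phenotypic heterogeneity —
for instance the true QTL's two-curve structure — even when the scanned
locus is completely unlinked, as on permuted genotypes. The permutation
threshold absorbs this inflation, but it dominates the null distribution
and makes permutation scans expensive. Replicate studies therefore scan
marker positions by default (`power_study()`'s `step` equals the reduced
map's marker spacing): at a RIL marker the conditional probabilities are
hard 0/1, the mixture has no such freedom, and LR profiles decay cleanly
with distance from the QTL. Interval positions remain available through
`genome_scan(step = ...)` for real analyses, where the same permutation
procedure keeps the comparison honest.

## The synthetic-data generator

`simulate_dataset()` emulates a soybean-like RIL design end to end:
genotypes from the two-state Markov chain along each linkage group
(default 25 groups, 950 markers, 100 cM each; fully homozygous lines),
one QTL placed at a marker, phenotypes equal to the genotype's ODE curves
plus i.i.d. Gaussian white noise per trait and occasion. The generating
parameter pair (`default_qtl_params()`) is the fitted two-genotype pair at
the second biomass QTL of the study this package's simulation design
emulates; genotype 1 carries the larger leaf allometric constant
($\alpha_L = 2.55$ vs 1.89). Noise is calibrated by
`heritability_to_sigma()`: at the middle measurement occasion $t^*$
(the third of six), the QTL's genetic variance for trait $k$ is
$\sigma_{g,k}^2 = \tfrac14 [\mu_{k,1}(t^*) - \mu_{k,2}(t^*)]^2$ (two
equal-frequency homozygote classes) and the residual variance solves
$h^2 = \sigma_g^2 / (\sigma_g^2 + \sigma^2)$, default $h^2 = 0.05$ per
trait. Everything is reproducible from a single integer seed.

Per-RIL measurement-time jitter and missing-completely-at-random record
drop-out are available as options (`time_jitter`, `dropout`), exercising
the ragged, progeny-specific time grids the likelihood supports. What the
generator does *not* emulate: genotyping error, segregation distortion,
informative missingness, cross-trait residual correlation,
genotype-by-environment interaction, and block/replicate structure of the
field design. Passing tests therefore
demonstrate statistical correctness of the machinery under the stated
white-noise model, not robustness to these real-data features.

### Initial states

The generating curves start at $(M_L, M_S, M_R) = (0.5, 0.3, 0.2)$ g at
$t = 2$ — a small seedling well below the leaf and root quasi-equilibria.
The resulting early transients are exactly what identifies the elimination
rates, which is why the default grid samples densely right after the first
occasion.

## Identifiability

Two facts about this design shape what users should expect from fits.

First, the root parameter triplet sits on a curved, *bimodal* likelihood
ridge: a "slow equilibration" solution (small $\gamma_R$, near-flat
exponent) fits the observable curves as well as the generating "fast
equilibration tracking a rising equilibrium" solution, because with
$1/\gamma_R \approx 0.46$ units most of the root transient falls between
even the dense early occasions. At $h^2 = 0.05$ the two basins differ by
less than 0.01 penalized log-likelihood units per replicate — and by only
about one unit under the exact ODE-constrained likelihood, with the sign
of the difference noise-driven — so which basin the maximum-likelihood
estimate lands in is effectively a coin toss decided by the data. The
consequence, verified over replicate studies with a fully converged
ridge-covering multi-start: per-replicate $\hat\gamma_R$ is bimodal
(clusters near 0.3–0.5 and near 2–2.7), and its replicate *mean*
underestimates the generating value by roughly 40%. No estimator can do
better from these data; a two-stage $\lambda$-continuation refinement was
evaluated during development and changed no basin choices. The leaf
triplet shows the same geometry much more weakly (mean biases around
+10–20% for $\alpha_L$, $\gamma_L$), and the stem parameters are well
determined (replicate SDs of a few hundredths).

Second, expected precision has a hard information bound, which
`design_information()` computes for any design (Fisher information of the
18 mean-curve values per genotype, auxiliary initial states marginalised).
Under the default grid at $h^2 = 0.05$, n = 184, the bounds are roughly
0.2–0.5 for the allometric constants and 0.4–1 for $\gamma_R$ — and
several-fold worse under uniform full-season sampling, which is how the
default occasions were chosen. Reported precisions meaningfully below
these bounds cannot come from this design; the package's replicate
studies report what the information supports.

## Desk-scale defaults

Replicate studies in the test-suite and the acceptance script run on a
reduced design chosen to fit on one CPU: a single 50-cM linkage group with
six markers scanned at marker positions, 50 replicates per arm for power
and false-positive rates with a shared 100-permutation threshold, and
20–30 replicates for parameter recovery. These sizes are the package's
reduced reference conditions; the full-scale equivalents (25 groups, 1000
permutations, 100 replicates, within-interval scan steps) use the same
code paths unchanged.

## Known limitations

* The cross-trait residual covariance is fixed at zero; correlated organ
  measurement errors would be mis-modelled.
* The shared-threshold approximation in `power_study()` ignores
  replicate-to-replicate threshold variation; for final inference on a real
  dataset run `permutation_threshold()` on that dataset itself.
* Estimates of weakly identified parameters (notably $\gamma_R$) should be
  reported with bootstrap intervals, not point values alone
  (`bootstrap_se()`).
* The single-QTL mixture scans one position at a time; linked QTLs on the
  same group will distort each other's profiles (no composite-interval or
  multi-QTL model).
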