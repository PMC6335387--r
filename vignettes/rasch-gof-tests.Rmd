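---
title: "Overall goodness-of-fit testing for the Rasch model: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Overall goodness-of-fit testing for the Rasch model: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raschgof)
```

## The model and the testing problem

The dichotomous Rasch model describes the probability that person $j$
solves item $i$ as

$$P(X_{ji} = 1 \mid \theta_j, \beta_i) = \frac{e^{\theta_j - \beta_i}}
{1 + e^{\theta_j - \beta_i}},$$

with a single ability parameter $\theta_j$ per person and a difficulty
$\beta_i$ per item.  The model buys its attractive measurement properties
(sufficiency of the raw score, separability of person and item parameters,
specific objectivity) with strong assumptions: unidimensionality, local
independence given $\theta$, and parallel item characteristic curves
(equal discriminations, zero lower asymptotes, invariant difficulties).
`raschgof` implements four overall tests of these assumptions and the
simulation machinery to study their type-I error and power:

* **LR** — Andersen's likelihood-ratio test.  Conditional maximum
  likelihood (CML) difficulties are estimated in the total sample and in
  two score groups (raw score at or above the median versus below);
  $LR = 2\left(\sum_c \ln L_c(\hat\beta_c) - \ln L(\hat\beta)\right)$ is
  referred to a $\chi^2$ with degrees of freedom equal to the parameters
  estimated in the groups minus those estimated overall — $(G-1)(n'-1)$
  for a shared set of $n'$ items.  A *first-order* test: it compares
  observed and expected single-item margins across groups.
* **T10, T11** — Ponocny's nonparametric quasi-exact statistics.  Both
  compare the observed matrix against matrices drawn uniformly from the
  set of 0/1 matrices with the *same row and column sums*, so neither
  needs parameter estimates or asymptotics.  T10 measures subgroup
  invariance through pairwise counts
  $\sum_{i<j} |N_{ij}^{(h)} N_{ji}^{(l)} - N_{ij}^{(l)} N_{ji}^{(h)}|$
  (first-order); T11 sums $|r_{ij} - \rho_{ij}|$ over item pairs, where
  $\rho$ is the mean inter-item correlation over the sampled matrices
  (second-order).
* **M2** — the Maydeu-Olivares–Joe limited-information statistic.  After a
  marginal maximum likelihood (MML) fit with a normal ability
  distribution, the residual between sample and model-implied moments up
  to order 2 is weighted by
  $C = \Xi^{-1} - \Xi^{-1}\Delta(\Delta'\Xi^{-1}\Delta)^{-1}\Delta'\Xi^{-1}$,
  giving $M_2 = N e' \hat C e \sim \chi^2_{s-q}$ with
  $s = n + \binom{n}{2}$ moments and $q = n + 1$ parameters.  A
  second-order omnibus test.

## Estimation back-ends

**CML.**  The conditional likelihood given the raw scores involves the
elementary symmetric functions (ESFs) $\gamma_r$ of the easiness
parameters $\varepsilon_i = e^{-\beta_i}$.  ESFs and their first and
second partial derivatives are computed in C++ by the summation
recursion, which is numerically stable up to the longest tests used here
(n = 50), unlike the difference algorithm.  `rasch_cml()` then runs
Newton iterations with the analytic gradient and Hessian, sum-zero
normalization, and step-halving; convergence requires the gradient
max-norm to fall below `1e-8` within 100 iterations.  Persons with
extreme raw scores (0 or n) carry no conditional information and are
excluded (and reported).  Near the optimum the Newton improvement can
fall below the floating-point resolution of a log-likelihood of size N;
step-halving therefore accepts candidates within a `1e-10` *relative*
band, which is what makes long-test fits (n = 30, 50) robust.

**MML.**  `rasch_mml()` fixes the ability mean at 0 and the slopes at 1
and frees the ability standard deviation, so $q = n + 1$ — the
parameterization that reproduces df $= s - q = 27$ for an 8-item test.
Because the raw score is sufficient under unit slopes, the E-step
posterior over the 61-node Gauss–Hermite grid depends on a person only
through the raw score; the EM cycle therefore works on score-collapsed
counts and costs $O(n \times 61)$ per cycle regardless of N.  The
M-steps are exact (per-item Newton for $\beta$, closed form for
$\sigma^2$), so the marginal log-likelihood is monotone along the
trajectory (up to quadrature error; the suite asserts this).
Convergence: largest absolute parameter change below `1e-5` within 500
cycles, mirroring common EM practice for this model.  61 quadrature
nodes put the moment integration error orders of magnitude below the
statistical noise at the sample sizes studied.

**M2 internals.**  $\Xi_{ab} = \pi_{a\cup b} - \pi_a \pi_b$ needs joint
moments up to order 4; these are quadrature sums over products of item
response curves, with the subset-union bookkeeping cached per test
length.  $\Xi$ is evaluated at the fitted model (the standard asymptotic
choice).  The statistic is computed in the orthogonal-complement form
$N e' U (U'\Xi U)^{-1} U'e$ with $U$ an orthonormal null-space basis of
$\Delta'$ — algebraically equal to the $C$ form (the suite checks the
identity to `1e-8`) but it avoids inverting the full $s \times s$
matrix.  Rank deficiency of $\Delta$ and ill-conditioning of $U'\Xi U$
(reciprocal condition below `1e-12`) are reported as errors.

## The margin-fixed sampler

T10/T11 need uniform draws from the set of 0/1 matrices with the
observed margins.  `sample_fixed_margins()` runs the rectangle-swap
Markov chain: pick two rows and two columns, flip the selected 2×2
submatrix if it is a checkerboard.  Two design details matter:

* Row and column indices are drawn independently *with replacement*.
  Coinciding indices give a hold move, which keeps the chain aperiodic.
  With forced-distinct pairs the chain is periodic exactly on the
  smallest reference sets (e.g. the two-element set of the 2×2
  checkerboard, where every distinct tetrad is swappable), which would
  bias the bootstrap where it is most transparent to verify.  For
  realistic matrices the hold probability is negligible.
* Burn-in and thinning default to `100 * sum(X)` and `2 * sum(X)`
  proposals: mixing time scales with the number of ones that can
  participate in swaps.  These are declared defaults, exposed in the
  API, not a reproduction of any particular package's settings.

The proposal kernel is symmetric and the chain connects the reference
set, so the stationary law is uniform; the suite verifies uniformity
against brute-force enumeration of a small reference set.  Matrices
whose margins determine them uniquely (no swappable tetrad) are flagged
and all p-values become 1.

Because rectangle swaps preserve row sums, the median score split of the
observed matrix applies verbatim to every sampled matrix; the package
computes the split once and asserts this invariance.  Ties at the median
go to the *high* group (the convention embedded in T10's definition),
and the same rule is used for the LR test so that both share one split
operation; the LR literature's "above or below the median" wording does
not resolve ties, so a single explicit convention was preferred.

For T11, $\rho$ is estimated from the same B draws used for the null
distribution rather than from a second independent sample — this
follows the two-step description of the statistic; it induces a slight
conservatism that is accepted and documented rather than corrected.
P-values use the add-one estimator $(1 + \#\{T_b \ge T_{obs}\})/(B+1)$,
standard exact-test practice that avoids zero p-values.

## The data generators

`sim_spec()` + `draw_condition_items()` + `sim_responses()` implement the
six generating models of the power study; the defaults *are* the study
conditions:

| family | violation | parameters (study levels) |
|---|---|---|
| `rasch` | none (null) | $\beta, \theta \sim N(0,1)$ |
| `surface_ld` | pairwise local dependence | overwrite 0.9 / 0.8; $\beta_1 = -0.626$, $\beta_2 = 0.184$ |
| `multidim` | two latent traits | $r = 0.3$ / $0.7$, items split half/half |
| `mixed_rasch` | latent-class DIF | 20% / 40% of items shifted by $-0.8$ for a 40% class |
| `twopl` | unequal discriminations | $\alpha \sim$ log-normal, log-variance 0.09 / 0.25 |
| `guessing` | nonzero lower asymptote | $\gamma = 0.1$ / $0.25$ |

Decisions taken where the design was genuinely open:

* The log-normal discrimination spread is read as a log-*variance* of
  0.09 / 0.25 (log-sd 0.3 / 0.5), matching the weak/strong wording and
  common simulation practice.
* Discriminations are drawn once per condition, alongside the
  difficulties, rather than redrawn per replication — parallel to the
  fixed-items convention; the alternative is not ruled out by the study
  description.
* Mixed-Rasch class membership is i.i.d. Bernoulli(0.4) per person (a
  stochastic 40%, not an exact quota), redrawn with the persons each
  replication.
* The multidimensional split assigns the first half of the items to
  trait 1; only "one half of the item set" is prescribed, and item order
  is exchangeable here.
* Surface local dependence is a post-processing step: among respondents
  with the dependent item solved but not the prerequisite, the
  prerequisite is overwritten to 1 with the stated probability.  The two
  special difficulties are forced into positions 1 and 2 of the drawn
  difficulty vector.

The generators emulate the study conditions, not empirical data: no
missing responses, no polytomous items, no guessing *strategies* (only a
constant asymptote), fixed person distribution.  Passing tests therefore
certify calibration and power *under these conditions*; behavior on real
data with, say, non-normal abilities is outside what the suite shows.

## The study harness

`run_condition()` draws item parameters once per condition (from the
condition seed), redraws persons each replication (from derived
replication seeds), runs the requested tests and tabulates rejection
rates with Monte-Carlo standard errors.  T10 and T11 share one
margin-fixed sample per replication.  Replications where a test errors
(degenerate data, non-convergence) are excluded from that test's
denominator and counted as failures — exclusion-with-reporting avoids
biasing rates while keeping the choice auditable.  Tables are
deterministic given the seeds, independent of execution order.

Default scales are desk-sized: 500 replications per condition (the
original study used 5,000) and B = 300 bootstrap matrices inside grids
(500 for single-dataset testing).  The acceptance script uses 200–1,000
replications per quantity; Monte-Carlo standard errors are reported
throughout so the reduced precision is visible rather than hidden.

## Known limitations

* The LR implementation supports only the median split (the global-test
  variant); splits by external covariates are out of scope.
* Missing data are rejected, not imputed.
* T10/T11 become computationally heavy for very large matrices (the
  chain length scales with the matrix mass); this mirrors the inherent
  scope of the nonparametric approach.
* M2 asymptotics are first-order: with few hundred persons its level can
  drift a percentage point or two above nominal for unlucky item draws,
  which the original study also reports for small samples and long
  tests.
* The empirical 346 × 8 cube-comparison dataset discussed in the
  acceptance suite ships with the third-party TAM package and is not
  redistributed; the corresponding check runs only when the user drops
  that dataset into `inst/extdata/cube346.csv`.
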