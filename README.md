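# raschgof

Overall goodness-of-fit tests for the dichotomous Rasch model, with the
simulation machinery to study their type-I error and power.

## The problem

The Rasch model describes the probability that respondent *j* solves item
*i* as

    P(X_ji = 1 | theta_j, beta_i) = exp(theta_j - beta_i) / (1 + exp(theta_j - beta_i))

and earns its measurement properties (raw scores sufficient for ability,
separable person and item parameters, specific objectivity) through strong
assumptions: one latent trait, local independence, and parallel item
characteristic curves.  Before interpreting a Rasch scale, practitioners
test those assumptions globally.  `raschgof` implements four such tests —
the ones a psychometrician would otherwise collect from several packages —
on one shared set of estimation and sampling back-ends:

| test | type | reference distribution | back-end |
|---|---|---|---|
| `lr_test()` | first-order | chi-square, df = (G−1)(n′−1) | conditional ML (elementary symmetric functions, C++) |
| `ponocny_test(, "T10")` | first-order | bootstrap over margin-fixed matrices | rectangle-swap MCMC (C++) |
| `ponocny_test(, "T11")` | second-order | bootstrap over margin-fixed matrices | rectangle-swap MCMC (C++) |
| `m2_test()` | second-order | chi-square, df = s − q | marginal ML, EM + Gauss–Hermite |

The LR statistic is `2 * (sum_c lnL_c(beta_c) - lnL(beta))` over median
score groups; T10 sums `|N_ij(h) N_ji(l) − N_ij(l) N_ji(h)|` over item
pairs; T11 sums `|r_ij − rho_ij|` between observed and null inter-item
correlations; M2 is `N e' C e` on the univariate and bivariate moment
residuals, with `s = n + n(n−1)/2` moments against `q = n + 1` parameters.

The package also ships the six data-generating models used to study these
tests — the Rasch null plus five violations (surface local dependence,
two correlated traits, latent-class DIF, log-normal discriminations,
pseudo-guessing) — and a Monte-Carlo harness (`run_condition()`,
`run_grid()`) producing rejection-rate tables with Monte-Carlo standard
errors.

## Worked example

Data from a 2PL model (log-normal discriminations, log-variance 0.25) are
a classic violation of parallel item characteristic curves; all four tests
should reject:

```r
library(raschgof)
set.seed(2025)
spec  <- sim_spec("twopl", log_var = 0.25)
items <- draw_condition_items(spec, 10)   # difficulties + discriminations
X     <- sim_responses(spec, 300, items)  # 300 persons x 10 items

lr_test(X)
#> 	Andersen likelihood-ratio test (median score split)
#> LR = 30.62, df = 9, p-value = 0.0003439

m2_test(X)
#> 	Maydeu-Olivares and Joe M2 limited-information test
#> M2 = 89.454, df = 44, p-value = 6.171e-05

ponocny_test(X, "T11", B = 500, seed = 7)
#> 	Ponocny T11 quasi-exact test (500 margin-fixed bootstrap samples)
#> T11 = 3.0943, p-value = 0.001996

ponocny_test(X, "T10", B = 500, seed = 7)
#> 	Ponocny T10 quasi-exact test (500 margin-fixed bootstrap samples)
#> T10 = 17328, p-value = 0.003992
```

All four p-values are small: the LR and T10 statistics react to the
unequal discriminations directly, T11 to the correlation structure they
induce, and M2 to the misfit of the bivariate moments.  The T10/T11
p-values are add-one bootstrap estimates over 500 matrices drawn
uniformly among all 0/1 matrices with the observed row and column sums,
so their granularity is 1/501.

Rejection-rate tables over a design grid come from the harness:

```r
cond <- sim_condition(sim_spec("multidim", r = 0.3), N = 100, n = 10,
                      reps = 500, seed = 1, B = 300)
run_condition(cond, tests = c("LR", "M2", "T11"))
# one row per test x alpha: rate, MC standard error, failures
```

A thin command line (`inst/cli/raschgof`) exposes `simulate`, `test` and
`study` subcommands over CSV matrices and YAML grid configs; see
`?raschgof_cli`.

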