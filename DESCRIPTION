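Package: raschgof
Title: Overall Goodness-of-Fit Tests for the Dichotomous Rasch Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Conditional and marginal maximum likelihood estimation of the
    dichotomous Rasch model together with four overall goodness-of-fit
    tests: Andersen's likelihood-ratio test on score groups, Ponocny's
    nonparametric T10 and T11 statistics with bootstrap p-values over
    uniform samples of binary matrices with fixed margins, and the
    limited-information M2 statistic of Maydeu-Olivares and Joe. Includes
    generators for Rasch data and five violation models (surface local
    dependence, two-dimensional abilities, latent-class differential item
    functioning, unequal discriminations, pseudo-guessing) and a
    Monte-Carlo harness for type-I-error and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    pracma,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
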