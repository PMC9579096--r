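Package: ordmi
Title: Scale- and Item-Level Measurement Invariance Testing for Ordinal Items
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Monte-Carlo machinery for comparing scale-level and item-level
    measurement-invariance (differential item functioning) testing with ordinal
    item responses. Provides a categorical factor-model / graded-response-model
    data generator with configurable loading and threshold non-invariance, a
    two-step polychoric estimator with asymptotic covariance matrix, a
    multiple-group categorical CFA engine fitted by diagonally weighted least
    squares with mean-and-variance-adjusted test statistics (chi-square
    difference tests, RMSEA, CFI), a multiple-group normal-ogive graded
    response model fitted by marginal maximum likelihood with likelihood-ratio
    DIF tests, ordinal logistic-regression DIF with McFadden pseudo-R-squared
    effect sizes, and an orchestrator that computes convergence, false-positive
    and true-positive rates over a simulation grid.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    mnormt,
    numDeriv,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
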