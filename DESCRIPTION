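Package: falsepower
Title: Residual Confounding and Type I Error Inflation from Error-Prone
    Covariate Measurement
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how the reliability of error-prone
    measurements of an exposure and a confounder drives spurious partial
    correlation and type I error inflation ("false power") when testing an
    exposure-outcome association adjusted for the confounder.  Implements
    standardized-normal path models with classical (true-score) measurement
    error, the implied correlation matrices, closed-form squared partial
    correlations and their derivatives, critical-point and monotonicity
    analysis, analytic false power via the noncentral F distribution, a
    vectorised Monte Carlo engine that verifies every analytic claim, and a
    grid search for cost-constrained study designs that trade sample size
    against instrument reliability.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
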