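Package: otesurv
Title: Linear-Regression-Like Residuals for Right-Censored Time-to-Event Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computes ordinary time-to-event (OTE) residuals, a survival-analysis
    residual with a linear-regression-like interpretation: it is zero exactly when
    an individual's (observed or predicted) event time equals the covariate-specific
    median survival time, and it measures deviation from that expectation on the
    cumulative-hazard scale. Censored individuals enter through their conditional
    median event time rather than their censoring time. The package also provides
    classical Martingale and deviance residuals, a naive linear residual, stratified
    right-censored Weibull maximum-likelihood estimation with Kaplan-Meier
    diagnostics, a genotype-mixture simulator for time-to-event genome-wide
    association designs, and a simplified posterior probability of linkage
    disequilibrium (PPLD) score for residual-phenotype association.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    survival,
    jsonlite,
    stats,
    graphics,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
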