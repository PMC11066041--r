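Package: lagriskr
Title: Distributed Lag Non-Linear Models with QAIC Selection and Multi-City Pooling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage multi-city time-series analysis of particulate matter and
    daily hospital admissions. Fits city-level distributed lag non-linear models
    (DLNMs) with a quasi-Poisson likelihood, selects meteorological covariates and
    cross-basis hyperparameters by best-subset enumeration ranked by QAIC with a
    delta-QAIC parsimony rule, reduces fitted cross-basis coefficients to
    relative-risk exposure-lag-response summaries, and pools city-level estimates
    by fixed-effect multivariate meta-analysis. Includes a synthetic multi-city
    panel generator with a known exposure-lag-response surface so the whole
    pipeline is testable by parameter recovery.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    splines,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
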