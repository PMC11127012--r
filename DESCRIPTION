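Package: baybloom
Title: Gap-Filled Trend and Bloom-Phenology Analysis for Weekly Estuarine
    Plankton Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for long-term weekly chlorophyll-a monitoring series:
    Bayesian dynamic-linear-model gap filling with forward-filtering
    backward-sampling, Monte-Carlo propagation of imputation uncertainty
    through seasonal ARIMA models with lagged environmental regressors,
    bivariate Granger-causality screening, threshold-based bloom phenology
    (start, peak, duration, frequency) with Poisson-GLM trend tests, and
    long-term trend statistics including decadal comparisons, log-linear
    fits, weekly climatologies and the k-sample Anderson-Darling test. A
    seeded synthetic-data generator emulates the statistical structure of a
    bimodal temperate estuary for end-to-end testing and calibration
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lmtest
Config/testthat/edition: 3
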