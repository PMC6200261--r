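Package: codcast
Title: Climate-Driven Multi-Year Prediction of Fish Stock Biomass
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for discovering and exploiting multi-year advective lags
    between upstream ocean climate indexes and fish stock biomass, in the
    style of statistical long-term forecasting of the Barents Sea cod stock.
    Provides lagged cross-correlation screening with phase-randomization
    (random phase) significance tests, lag-l multiple linear regression
    forecast models with residual diagnostics and collinearity handling,
    Monte-Carlo 80/20 cross-validated skill scoring (anomaly correlation and
    the variance-ratio Brier score) against lagged-persistence and
    random-chance benchmarks, attribution of prediction error to fishing
    pressure, and a synthetic scenario generator with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    lmtest,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
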