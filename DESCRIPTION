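Package: riskimpute
Title: Imputation and Probabilistic Forecasting for Risk Calculators with
    Systematically Missing Inputs
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates outputs of deterministic disease-risk calculators when
    some inputs are systematically missing, and evaluates the resulting point
    and probabilistic risk forecasts. Implements the SCORE2 10-year
    cardiovascular risk model with region calibration, five imputation-to-risk
    methods (sample-mean patching, pooled and probabilistic multiple
    imputation by chained equations with predictive mean matching, and
    Gaussian-copula conditional-mean and conditional-distribution
    propagation), proper scoring rules (CRPS and threshold Brier scores),
    cut-off-probability classification with ROC sweeps, a leave-one-out
    benchmark harness, and a synthetic-cohort generator emulating a female
    menopause-clinic population.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    knitr,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
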