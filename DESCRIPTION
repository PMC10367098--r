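Package: sekrige
Title: Geostatistical Mapping of Plasma Selenium Status from Biomarker Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the geostatistical analysis of georeferenced micronutrient
    biomarker surveys, built around plasma selenium. Provides exploratory
    diagnostics (summary tables, octile-skewness normality gate, GPS exclusion
    rules, inflammation-correlation screening), empirical semivariograms by the
    Matheron and Cressie-Hawkins robust estimators, residual maximum likelihood
    (REML) estimation of nugget/partial-sill/range parameters under a
    constant-mean spatial linear mixed model, ordinary kriging with
    leave-one-out cross-validation and model selection by the median
    standardized squared prediction error, polygon-clipped prediction and
    kriging-variance grids, conditional probabilities of falling below
    selenoprotein-activity thresholds reported on the IPCC calibrated verbal
    scale, and threshold-based prevalence tables. A synthetic-survey generator
    simulates cluster-sampled Gaussian random fields with known parameters so
    every stage of the pipeline can be verified by parameter recovery and
    cross-validation calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    mgcv,
    nlme,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
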