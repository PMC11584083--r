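Package: flockfit
Title: Growth-Curve and Spline Models for Broiler Body-Weight Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits five classical sigmoidal growth models (logistic, Gompertz,
    Weibull, Hossfeld and von Bertalanffy) to longitudinal age-weight records
    from poultry flocks, with closed-form inflection points, deterministic
    multi-start nonlinear least squares, and a single-predictor implementation
    of multivariate adaptive regression splines (MARS) with generalized
    cross-validation pruning. Includes goodness-of-fit criteria (MSE, RMSE,
    R-squared, AIC, BIC), cross-model ranking, a seeded simulator of flock
    weighing data with per-bird asymptote heterogeneity and heteroscedastic
    measurement noise, report generation, and ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
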