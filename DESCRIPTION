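Package: heartage
Title: Bayesian Heart-Age Prediction from ECG-Derived Outputs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Estimates a subject's "heart age" from electrocardiographic
    (ECG) outputs with a Bayesian posterior-mean shrinkage estimator. The
    prior on heart age is Normal, centered at chronological (body) age with
    a 7.5-year standard deviation; ECG outputs enter through a
    quadratic-in-age regression with a latent heart-age drift term, and the
    posterior mean is available in closed form. Includes gender-stratified
    model fitting from cohort data, variance-component estimation of the
    measurement-noise covariance from month-apart repeated ECGs, published
    composite ECG scores and model constants, a synthetic-cohort simulator
    for end-to-end validation, and evaluation utilities (shrinkage slope,
    group-level calibration, gender-specific versus pooled model
    comparison).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
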