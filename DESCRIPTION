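Package: wsgait
Title: Weighted Multi-Scale Convolutional Networks for Inertial Gait Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identification and verification of walkers from smartphone
    inertial signals (tri-axial accelerometer and gyroscope windows). Implements
    a weighted multi-scale one-dimensional convolutional network: windows are
    coarse-grained by non-overlapping block averaging at several time scales,
    each scale is processed by an independent 1D CNN, and a Fisher-discriminant
    weight-update branch converts localized class scores into per-feature
    weights before a learned fusion layer produces a global feature for
    classification. Includes a synthetic quasi-periodic gait-signal generator
    with covariate perturbations (speed change, asymmetric load, pocket
    damping), gallery/probe evaluation (rank-k identification rates, ROC,
    verification rate at fixed false-acceptance rate), and tidy accessors for
    fitted models and reports.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
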