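Package: canalarea
Title: Lumbar Spinal Canal Area Approximation from Linear CT Measurements
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates the cross-sectional area of the lumbar spinal canal
    (L1-L5) from two linear CT measurements, the interpedicular distance and
    the anteroposterior canal diameter, using closed-form ellipse, triangle
    and rectangle approximations. Quantifies agreement between each
    approximation and manually traced canal area per vertebral level (mean
    difference, paired t-test, aggregate percent error, Pearson correlation),
    fits a second-order approximation as a least-squares scale factor on the
    diameter product with k-fold cross-validation, and simulates
    moment-calibrated synthetic cohorts whose per-level means, standard
    deviations and estimator-measurement correlations match published summary
    statistics, so the full pipeline runs without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
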