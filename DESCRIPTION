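Package: broilervision
Title: Non-Invasive Broiler Live-Weight Estimation from Morphometrics and
    Top-View Images
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A three-stage pipeline for estimating broiler chicken live
    weight without handling the birds: Richards sigmoidal growth-curve
    fitting of daily weight records; a supervised machine-learning
    benchmarking harness (random forest, gradient boosting, epsilon-SVR,
    k-nearest neighbours and multiple linear regression) predicting live
    weight from back length and back width with repeated random
    sub-sampling validation and exact two-feature Shapley attribution; and
    a computer-vision workflow that segments a bird against a black
    reference floor in top-view images, counts projected body-surface
    pixels, and regresses log live weight on age, log pixel area and their
    interaction. A synthetic-cohort generator emulates the measurement
    design (100 birds, 42 daily records each, five replicate images per
    bird-day) so every stage is exercisable end-to-end without the
    original data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    png,
    quadprog,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    FNN,
    withr,
    optparse
Config/testthat/edition: 3
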