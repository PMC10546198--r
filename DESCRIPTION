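Package: fundusplus
Title: Harmonization and Cost-Weighted Classification of Smartphone
    Fundus Images for Plus Disease Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for retinopathy-of-prematurity screening from
    smartphone fundus photographs: a deterministic image harmonization
    pipeline (green channel, Hough-circle fundus masking, unsharp
    masking, contrast limited adaptive histogram equalization, Gaussian
    smoothing, resizing to a common 800x800 geometry), the contrast
    improvement index for quantifying enhancement, class-imbalance
    handling by eightfold geometric augmentation with randomized
    balanced selection, a real-world-weight (dollar-cost) cross-entropy
    loss, a small convolutional classifier with class activation maps,
    ROC and cost-based evaluation, and a synthetic preterm-retina
    generator so the whole workflow is testable without patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jpeg,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
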