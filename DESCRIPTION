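Package: ssnradiomics
Title: CT Attenuation Histogram Features and Density FPCA for Subsolid
    Lung Nodule Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An analysis pipeline that classifies subsolid lung nodules as
    invasive versus pre-invasive/minimally-invasive adenocarcinoma from CT
    attenuation histograms and geometric measurements. Provides a seeded
    synthetic cohort generator calibrated to published per-class feature
    distributions, a-priori histogram features (moments, quantiles,
    consolidation ratio, geometry), functional principal component analysis
    of attenuation densities in the log-quantile-density domain, univariate
    ROC screening with Youden thresholds, repeated stratified k-fold
    cross-validated logistic models with bootstrap calibration curves, and
    inter-reader agreement statistics (Cohen's kappa, ICC).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
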