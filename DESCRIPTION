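Package: lipidscreen
Title: Quantitative Serum Lipidomics Screening with OPLS-DA Classification
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for lipidomics-based cancer screening
    from serum: internal-standard quantitation of centroided mass-spectral
    peak lists (intensity thresholding, accurate-mass database matching,
    isotope correction, class internal-standard ratioing), cohort-level
    preprocessing (presence filtering, zero imputation, reference-plasma
    normalization, log transformation with unit-variance or Pareto scaling,
    stratified train/validation splitting), gender-stratified OPLS-DA
    classification with cross-validated Q2, VIP scores, S-plot coordinates
    and ROC/AUC diagnostics, univariate dysregulation statistics (Welch
    test, Bonferroni correction, fold-change screening), CA 19-9
    comparison and combination, and Kaplan-Meier/Cox survival analysis on
    median-dichotomized lipid concentrations.  A synthetic-cohort and
    synthetic-spectrum generator reproduces the statistical structure the
    analysis assumes, so the full pipeline can be exercised and validated
    without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    survival
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
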