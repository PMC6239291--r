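Package: vivorate
Title: Non-Invasive Video and CT Assays of Radiation-Induced Lung Injury in Mice
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: A toolkit for quantifying radiation-induced lung damage in small
    animals from non-invasive measurements. Implements camera-based
    respirometry (Shi-Tomasi feature detection, pyramidal Lucas-Kanade
    tracking, and spectral respiratory-rate estimation from the resulting
    motion waveform), threshold-based healthy-lung segmentation and
    seven-ROI densitometry for thoracic CT volumes, and the cohort
    statistics used in preclinical radiation studies: control-based
    mean +/- k*SD dichotomization, Hill dose-response fits with
    extra sum-of-squares F-tests on ED50, Kaplan-Meier/log-rank and Cox
    survival comparisons, Welch t-tests and Spearman correlations.
    Ships seeded synthetic generators (breathing video clips, two-lung
    density phantoms, dose-response cohorts) so every pipeline stage can
    be validated against known ground truth without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    mgcv,
    png,
    pracma,
    stats,
    survival,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
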