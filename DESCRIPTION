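Package: stresswave
Title: Heart-Rate-Informed GLM Analysis of fMRI Stress Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Mass-univariate analysis of block-design fMRI stress tasks in
    which the per-block heart rate (or high-frequency heart-rate
    variability) extracted from pulse plethysmography is used as a
    parametric modulator of the task regressor. Provides task-paradigm and
    hemodynamic-response modelling, photoplethysmography beat detection
    with inter-beat-interval artifact filtering and spectral
    heart-rate-variability analysis, anatomical-CompCor nuisance
    regression, voxelwise GLM fitting with contrasts, random-effects group
    t-tests with family-wise-error control and cluster reporting,
    region-of-interest timecourse and effect-size comparisons, correlation
    of heart-rate swing metrics with subjective ratings under an
    effective-number-of-tests correction, and a fully synthetic cohort
    generator with known ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    signal,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
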