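Package: erpmkl
Title: ERP Feature Extraction, Boruta Selection and Multiple-Kernel SVM
    Classification for Oddball Paradigms
Version: 0.1.0
Authors@R: person("ERP-MKL", "Maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Simulates oddball-paradigm event-related potential (ERP) cohorts
    (auditory/visual P300 and mismatch negativity), preprocesses continuous
    recordings into per-class averaged ERPs (zero-phase Butterworth bandpass,
    epoching, baseline correction, artifact rejection, averaging), extracts a
    726-column morphological and spectral feature table, standardizes and
    sigmoid-squashes features, performs all-relevant feature selection with a
    shadow-variable random-forest wrapper (Boruta), and classifies subjects
    with a multiple-kernel support vector machine trained by alternating
    lp-norm optimization, evaluated under nested stratified cross-validation
    with accuracy, sensitivity, specificity and AUC.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
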