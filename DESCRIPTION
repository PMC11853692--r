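Package: erpmvpa
Title: Time-Resolved Multivariate Decoding of Auditory Oddball ERPs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Single-subject multivariate pattern analysis (MVPA) of
    event-related potentials from auditory oddball paradigms. Provides a
    synthetic multi-block oddball EEG generator with controllable mismatch
    negativity (MMN) and P3a components and block-level waxing/waning gain;
    an offline preprocessing chain (zero-phase Butterworth band-pass and
    notch filtering, mastoid re-referencing, baseline correction,
    amplitude-threshold artifact rejection, superblock concatenation,
    undersampling class balance); time-resolved linear support-vector
    machine decoding with nested z-scoring and pseudo-trial averaging
    inside repeated stratified cross-validation, temporal generalization
    matrices and channel-by-window searchlight maps scored by ROC AUC;
    cluster-based permutation inference for single-subject significance;
    component amplitude extraction and amplitude-AUC correlation; and
    per-block tracking of decoding fluctuations with plotting and
    machine-readable outputs.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo:
    Rcpp
Imports:
    Rcpp,
    e1071,
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    pROC,
    yaml
Config/testthat/edition: 3
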