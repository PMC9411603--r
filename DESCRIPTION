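Package: dseresnet
Title: Two-Dimensional 12-Lead ECG Arrhythmia Classification with a
    Detached Squeeze-and-Excitation Residual Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classifies normal rhythm and eight cardiac arrhythmias from
    12-lead electrocardiograms by splicing the leads into a two-dimensional
    voltage image, conditioning it with zero-phase Butterworth band-pass
    filtering and symmetric min-max normalization, slicing long records into
    overlapping 8192-sample windows, and feeding the slices to a residual
    convolutional network with a detached squeeze-and-excitation channel
    attention module and age/sex auxiliary inputs.  Includes a synthetic
    12-lead ECG generator with class-conditioned P-QRS-T morphology, a
    pairwise (strength-2) covering-array designer for hyper-parameter
    screening, stratified record-level cross-validation with single-optimal
    model selection, majority-vote ensembling, and a full evaluation suite
    (per-class and macro F1, accuracy, sensitivity, specificity, grouped
    sub-abnormal F1).  Readers and writers for CPSC2018-style MATLAB files,
    WFDB record pairs, and label manifests are provided.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
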