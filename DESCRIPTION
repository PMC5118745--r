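Package: scgsti
Title: Sliding-Template Annotation of Systolic Time Intervals in Seismocardiograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automatic annotation of aortic-valve opening (AO), aortic-valve
    closure (AC) and mitral-valve opening (MO) fiducial points in
    seismocardiogram (SCG) recordings aligned by ECG R-peaks, using an
    ensemble-averaged initial template and a per-beat sliding template to
    track the low-amplitude diastolic peaks robustly. Derives the systolic
    time intervals PEP, LVET and QS2 per beat, and ships the matching
    evaluation machinery (misclassified-peak counts, Bland-Altman limits of
    agreement, SNR-controlled noise injection, parameter grid search) plus a
    seeded synthetic ECG+SCG generator with exact ground-truth fiducials.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    signal,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
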