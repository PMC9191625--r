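Package: eegbaf
Title: Single-Channel EEG Brain-Activity Features and Cognitive-Load Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing single-channel frontal EEG recorded during an
    auditory cognitive assessment. Implements a windowed wavelet-packet
    decomposition with best-basis selection and hard-threshold denoising, a
    fixed 121-component "brain activity feature" (BAF) library with per-second
    activations, classical band powers in dB, linear discriminant and
    principal-component derived EEG features, generation and scoring of an
    auditory detection battery, a synthetic cohort generator emulating groups
    defined by Mini-Mental State Examination (MMSE) scores, and the
    accompanying statistical pipeline: Pearson and age-partialled correlations
    with Fisher-z intervals, dependent-correlation comparisons, BCa bootstrap
    equivalence tests, Welch t-tests, linear mixed models with random task
    slopes selected by likelihood-ratio ladders, and Tukey, Bonferroni and
    Benjamini-Hochberg post-hoc corrections.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    lme4,
    lmerTest,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    boot
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
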