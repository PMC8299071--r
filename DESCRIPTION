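Package: pupilload
Title: Pupillometry-Based Cognitive Workload Indicators
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes the Index of Pupillary Activity (IPA), a wavelet-based
    pupillometric indicator of cognitive workload, from binocular
    pupil-diameter recordings: per-eye transient-event rates via modulus
    maxima of Symlet-16 detail coefficients and universal-threshold
    denoising, between-eye mean and absolute-difference channels,
    within-participant z-standardization, fixation precision and accuracy
    scoring, and a battery of JZS Bayes-factor paired comparisons across
    task conditions.  A synthetic binocular session generator with full
    ground truth makes every stage testable without raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    tidyr,
    withr
Config/testthat/edition: 3
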