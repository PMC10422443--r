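Package: swaysense
Title: Wearable Postural-Sway Detection and Fall-Risk Diagnostics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying postural sway from a chest-worn triaxial
    accelerometer and evaluating its value as a fall-risk screen. Converts
    3-axis acceleration (in G, nominally 50 Hz) into full-range inclination
    angles, extracts windowed sway features (per-second amplitude and 3-second
    root-mean-square series) per anatomical direction, and scores cohorts
    against clinical fall criteria (Berg Balance Scale, Timed Up and Go, fall
    history) with ROC/AUC analysis, Hanley-McNeil confidence intervals,
    Youden-index cut-offs, and sensitivity/specificity/accuracy grading.
    Includes a seeded synthetic-cohort simulator (score-level Gaussian groups
    and raw band-limited sway signals) so the full pipeline is testable
    without clinical data, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
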