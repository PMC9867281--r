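Package: emgait
Title: EMG-Onset Step Triggering and Gait Muscle-Synergy Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Offline implementation and analysis chain of an EMG-onset
    exoskeleton step-trigger controller: single-threshold onset detection on
    raw surface EMG, double-threshold offset detection on the linear envelope,
    baseline-driven per-muscle threshold calibration, and a redundant
    muscle-pair step-trigger state machine. The analysis side provides EMG
    envelope extraction (rectification + low-pass Butterworth), gait-cycle
    segmentation and 0-100% time normalization, muscle-synergy extraction by
    non-negative matrix factorization with reconstruction quality (VAF), full
    width at half maximum and center of activity of the basic activation
    patterns, per-cycle joint-angle summaries (max/min/ROM), and nonparametric
    condition comparison (Friedman + Wilcoxon signed-rank with Bonferroni
    correction). A seeded synthetic gait-EMG simulator with known ground truth
    (synergy structure, burst phases, corrupt channels, joint extrema) makes
    the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
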