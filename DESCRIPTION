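Package: headshakeR
Title: Objective Quantification of Equine Headshaking from Poll-Mounted
    Accelerometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting and characterising high-g vertical head
    movements in poll-mounted accelerometer recordings of lunged horses.
    Implements gravity correction, threshold-and-width peak detection on the
    vertical axis, a per-recording movement feature set (peak counts, rates,
    amplitudes and the percentage of peaks beyond 2 g), nonparametric
    group comparisons, per-feature ROC evaluation with constrained threshold
    selection and predictive values, published diagnostic threshold rules for
    trigeminal-mediated headshaking (TGMHS), and a seeded generator of
    group-structured synthetic cohorts (control, forelimb-lame, non-TGMHS
    and TGMHS head-movement profiles) so the whole pipeline is testable
    without device recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    pROC,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
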