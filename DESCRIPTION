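Package: phonoformant
Title: Formant-Based Phonocardiogram Analysis for Pulmonary Hypertension Screening
Version: 0.1.0
Authors@R: person("phonoformant", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Speech-inspired analysis of digital-stethoscope heart-sound
    recordings for non-invasive screening of pulmonary artery hypertension
    (PAH). Recordings are resampled and framed, an 8th-order linear
    predictive coding (LPC) analysis tracks the four strongest spectral
    resonances ("formants") per 32-ms window, a sine-wave replica isolates
    each formant trajectory, and a spectrogram log-power entropy feature
    quantifies how ordered (vowel-like) each formant is. Cohort-level
    tooling covers pooled-variance two-sample t-tests (raw and
    summary-statistic), Holm-Bonferroni step-down correction, recording-site
    and window-length selection, one-dimensional linear discriminant
    analysis with leave-one-out cross-validation, and a post-hoc power
    calculation. A synthetic multi-site phonocardiogram cohort generator
    makes the whole pipeline testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
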