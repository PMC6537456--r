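Package: swefatigue
Title: Neuromuscular Fatigue Metrics from Torque, EMG and Shear-Wave
    Elastography Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for quantifying neuromuscular fatigue during
    repeated isometric maximal voluntary contractions of the knee extensors.
    Extracts voluntary and electrically evoked torque metrics (MVC peak,
    doublet and twitch amplitudes, electromechanical delay, contraction and
    half-relaxation times, maximal rates of torque development and
    relaxation), voluntary activation level by the interpolated-twitch
    technique, surface EMG metrics (plateau RMS, M-wave peak-to-peak
    amplitude, normalization), and resting muscle shear elastic modulus from
    shear-wave-speed maps.  Includes a calibrated synthetic cohort generator
    that renders torque traces, EMG traces and elastography clips for a
    15-subject, 60-MVC fatigue protocol, plus repeated-measures ANOVA,
    Fisher LSD post hoc tests, ICC/SEM reliability statistics and a
    noncentral-F power calculation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    data.table,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    ggplot2
Config/testthat/edition: 3
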