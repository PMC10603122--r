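Package: vcfatigue
Title: Neurophysiological Videoconference-Fatigue Analysis Pipeline
Version: 0.1.0
Authors@R:
    person("Artifact", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis toolkit for videoconference-fatigue
    experiments combining EEG, ECG and self-report questionnaires. Provides a
    synthetic-data generator with controllable fatigue signatures (band-power
    drifts, event-related potential modulation, heart-rate and heart-rate
    variability trends, latent-fatigue-coupled ordinal questionnaire items), the
    matching signal-processing chain (zero-phase FIR filtering, comb notch,
    wavelet-enhanced ICA, Welch band powers, oddball ERP epoching, Pan-Tompkins
    QRS detection, windowed HRV indices) and the statistical linking models
    (mass-univariate linear mixed effects, Wilcoxon signed-rank comparisons with
    Benjamini-Hochberg correction, linear trend tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
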