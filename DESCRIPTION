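Package: semg2angle
Title: Continuous Lower-Limb Joint-Angle Estimation from Surface EMG
Version: 0.1.0
Authors@R:
    person("Artifact", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating continuous hip, knee and ankle joint angles
    from multi-channel surface electromyography (sEMG). Implements the full
    offline pipeline: Butterworth band-pass / notch filtering and envelope
    extraction of raw sEMG, joint-angle computation from motion-capture
    marker triples via the cosine formula, resampling onto a common 20 Hz
    analysis rate, sliding-window dataset construction, a cascaded temporal
    convolutional network with a convolutional block attention module
    (TCN - CBAM - TCN) regressor together with encoder-decoder TCN, plain
    TCN, LSTM and Wiener-filter baselines, a step-decay Adam training recipe,
    5-fold cross-validation with R-squared / RMSE / NRMSE metrics, and
    one-way ANOVA with Tukey HSD model comparison. A synthetic-session
    simulator with a known activation-to-angle forward model makes the whole
    pipeline testable without human recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
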