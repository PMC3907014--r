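Package: gaitbci
Title: EEG Motor-Imagery Decoding for Brain-Controlled Gait
Version: 0.1.0
Authors@R:
    person("BCI", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Offline training and online simulation of a two-state
    (idling vs. walking) electroencephalography brain-computer interface
    for robotic gait control. Implements spectral band-power feature
    extraction, classwise principal component analysis with an
    information-theoretic one-dimensional discriminant, a linear Bayesian
    classifier with stratified cross-validation and greedy frequency-band
    optimization, a sliding-window online decoder with posterior averaging
    and a dual-threshold finite state machine, session performance metrics
    (lagged cross-correlation, omissions, false alarms), an autoregressive
    surrogate model for Monte-Carlo significance testing, synthetic
    cue-locked EEG/EMG/gyroscope generators, and electromyographic
    validation of decoded walking epochs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
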