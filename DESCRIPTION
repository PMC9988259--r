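Package: recalibr
Title: Simulation and Analysis of Visual-Vestibular Recalibration Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing unsupervised cross-modal recalibration in
    heading-discrimination experiments. Provides a synthetic-data generator
    for the three-block cue-conflict paradigm (pre-recalibration single-cue
    testing, a gradual discrepancy ramp with combined-cue stimuli, and
    post-recalibration testing), maximum-likelihood cumulative-Gaussian
    psychometric fits with point-of-subjective-equality (PSE) shift
    estimation, reference-anchored ROC neurometrics for single-neuron tuning
    shifts (including bootstrap reliability screening and time-resolved
    sliding-window variants), heading/choice partial-correlation
    decomposition of trial-by-trial firing rates, and population-level
    statistics (signed-shift pooling, neuronal-perceptual correlations, and
    pooled-versus-mixed-model comparison).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    lme4
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
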