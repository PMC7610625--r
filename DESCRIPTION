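Package: tremorloop
Title: Closed-Loop Deep Brain Stimulation Simulation and Decoding for
    Essential Tremor
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for developing and evaluating closed-loop deep brain
    stimulation (DBS) strategies for essential tremor driven by thalamic
    local field potentials (LFPs). Provides a physiologically structured
    synthetic session generator (movement-related beta desynchronization,
    postural theta increase, delayed 3-7 Hz tremor, 130 Hz biphasic
    stimulation artifact with aliasing at 2048 Hz sampling), causal
    Butterworth preprocessing in second-order sections, band-power and
    time-domain feature extraction on a 100 ms update grid, data-driven
    movement/tremor labeling from EMG and accelerometry, training and
    block-wise cross-validation of per-stimulation-state classifiers
    (SVM, logistic regression, LDA, naive Bayes, decision tree, KNN,
    hierarchical extreme learning machine), support-vector regression of
    tremor intensity, a 10 Hz on/off stimulation controller with a
    closed-loop simulation harness, and the full evaluation suite
    (confusion rates, false-negative episode durations, tremor band
    power, delivered-energy index, anticipation latency, paired tests).
    Sessions are read and written as delimited tables or EDF.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    e1071,
    MASS,
    rpart,
    class,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
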