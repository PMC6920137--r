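Package: hfoLSTM
Title: Threshold Detection and LSTM Classification of Epileptiform
    Events in Intracranial EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects and classifies interictal epileptiform events
    (spikes, ripples, ripples-on-spikes and baseline activity) in
    multichannel intracranial EEG. Candidate events are nominated by a
    robust spectral threshold detector: short-time band power in eight
    physiological bands is normalised by a per-band baseline estimated
    from the mode region of the log-power distribution, and relative
    power thresholds label each 0.25 s bin. Candidates feed a small
    bidirectional LSTM sequence classifier trained on balanced event
    sets, with multi-class accuracy, sensitivity and specificity
    reporting over randomised train/test splits. Includes a calibrated
    synthetic iEEG generator (1/f background with injected spike,
    ripple and ripple-on-spike morphologies and inter-subject
    variability) and minimal EDF input/output, so the whole pipeline is
    testable without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    yaml,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
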