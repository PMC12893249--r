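Package: spikeloop
Title: Closed-Loop Detection of Interictal Epileptiform Discharge Bursts and
    Their Behavioral Effects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis toolkit for closed-loop assessment of
    interictal epileptiform discharge (IED) bursts in single-channel EEG.
    Generates labeled synthetic EEG containing spike-wave bursts, frames the
    signal into overlapping windows, encodes each window as a Markov
    Transition Field image, trains a small residual convolutional network
    with a focal balanced cross-entropy loss under explicit class
    rebalancing, simulates the real-time trigger loop (streaming, digital
    latency, refractory logic) together with a virtual subject performing a
    driving-obstacle task or brief cognitive probes, and computes the full
    suite of detection and effect statistics: window- and event-level
    sensitivity and specificity, false-positive trigger rate per minute,
    reaction-time prolongation, crash probabilities, a calibrated cumulative
    crash-risk curve, cognitive error/miss probabilities, and nonparametric
    cohort summaries with distribution-free confidence intervals for the
    median.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    jsonlite,
    yaml,
    pROC
Suggests:
    testthat (>= 3.0.0),
    optparse,
    png
Config/testthat/edition: 3
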