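Package: meaburst
Title: MaxInterval Burst and Network-Burst Analysis for Multi-Electrode
    Array Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects spikes, reverberations, bursts and network bursts in
    multi-well multi-electrode array (MEA) recordings of cultured neuronal
    networks.  Spikes are found by a +/-5 SD threshold around a baseline
    estimated from quiet 200-ms segments; reverberations are detected per
    channel with the five-parameter MaxInterval method and merged into
    bursts with a strict sub-300-ms gap rule; well-level network
    reverberations and network bursts follow a two-thirds participation /
    one-half simultaneity criterion.  Eight network-dynamics outcome
    measures (mean firing rate, percentage of random spikes, network burst
    rate, network inter-burst interval and its coefficient of variation,
    network burst duration, network reverberation duration and network
    burst composition) are computed per well.  A compact 1-D convolutional
    network regresses the three data-dependent MaxInterval parameters from
    5-s windows of binned signal or spikes, and a seeded synthetic-MEA
    simulator produces recordings and labelled training windows with full
    ground truth so every stage is trainable and testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    signal
Suggests:
    rhdf5,
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
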