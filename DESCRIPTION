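Package: somnosense
Title: Sleep Staging from Noncontact Piezoelectric Pressure Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for Wake/REM/NREM sleep staging from a single-channel
    piezoelectric pressure signal recorded under the pillow or mattress.
    Separates the raw signal into ballistocardiogram (BCG), respiration and
    body-movement components; estimates heartbeat and respiratory intervals
    on multiple timescales with movement-aware overlap weighting; assembles
    a 41-feature description of each 60-second epoch (independent heartbeat,
    respiratory and movement features plus cardiorespiratory coordination
    ratios); classifies epochs with standard machine-learning classifiers
    under recording-level leave-one-out cross-validation; and smooths the
    predicted hypnogram with a rule-based stage-fusion postprocessor.
    Includes a synthetic all-night vital-signs simulator with exported
    ground truth so the whole pipeline is testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    signal,
    zoo,
    pracma,
    randomForest,
    e1071,
    rpart,
    class,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
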