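Package: olfactrain
Title: Automated Go/No-Go Olfactory Training: Controller, Sequencer, Virtual Rig and Analytics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational core of an automated, RFID-gated go/no-go olfactory
    training system for group-housed mice. Implements the trial state machine
    and staged seven-phase pre-training curriculum, constrained pseudo-random
    S+/S- trial sequencing with counterbalanced odor-reward assignment, a
    virtual rig (stochastic learning agents with circadian activity and a
    synthetic dual-channel olfactometer) for end-to-end simulation without
    hardware or animals, and behavioral analytics: windowed fraction correct,
    signal-detection d-prime, trials-to-criterion, circadian activity
    profiles, group-size correlations and odor-pulse onset/peak metrics.
    Event logs are plain delimited text with a validating reader/writer and a
    command-line interface for simulation, sequence generation, validation
    and analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
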