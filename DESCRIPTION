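Package: adbci
Title: Auto-Calibrating Adaptive ERD-Based Brain-Computer Interfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation framework for auto-calibrating, adaptive brain-computer
    interfaces driven by event-related desynchronization (ERD) of EEG band power.
    Implements bipolar-derivation montages on a 10/20 electrode grid, trial-based
    multi-phase outlier rejection (amplitude, kurtosis/probability, iterative
    band-power), causal logarithmic band-power features with Fisher-criterion band
    selection, linear discriminant calibration with leave-one-out selection of a
    0.5 s training window, automatic class-pair selection among four mental tasks,
    a prequential online-simulation engine with periodic recalibration (Mini, SMR
    and Auto configurations), channel/class ranking sweeps, exact binomial chance
    bounds, and a seeded generator of synthetic cue-paradigm EEG sessions with
    class-conditional ERD, 1/f background noise and artifact injection.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    signal,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
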