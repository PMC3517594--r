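Package: cvep
Title: Adaptive Code-Modulated VEP Brain-Computer Interface Simulation and Decoding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and studying a code-modulated visual evoked
    potential (c-VEP) brain-computer interface speller in closed loop.
    Implements maximal-length binary modulation sequences with circular-shift
    target multiplexing, canonical-correlation spatial filtering with
    leave-one-out best-channel selection, one-class SVM template learning with
    minimum Euclidean-distance classification, online classifier adaptation
    (supervised co-adaptive calibration, unsupervised self-training,
    adaptation gated by error-related potential detection, and two-target
    calibration with label flipping), feedback-locked error-potential
    detection, and performance evaluation (accuracy, Wolpaw information
    transfer rate, error-free letters per minute). A synthetic multichannel
    EEG generator and a closed-loop experiment harness make every stage
    testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    signal,
    jsonlite,
    yaml,
    tibble,
    dplyr,
    rlang,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    optparse,
    withr
Config/testthat/edition: 3
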