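Package: emgpr
Title: Surface EMG Pattern Recognition for Myoelectric Prosthetic Control
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Desk-scale re-implementation of a myoelectric prosthetic-hand
    control stack: sliding-window FFT spectral features from 3-channel
    forearm surface EMG, teacher-data labeling, a small sigmoid multilayer
    perceptron for motion-intention classification, and a ring-buffer
    majority-vote filter that stabilizes the prediction stream. Includes a
    seeded synthetic surface-EMG generator emulating the analog sensor
    chain (band-limited Gaussian noise, 50-Hz mains pickup, 12-bit ADC,
    electrode-shift perturbations) so the full pipeline - simulate, label,
    train, classify, stabilize, evaluate - runs and is testable without
    hardware.
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
    jsonlite,
    signal,
    ggplot2,
    generics,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    nnet,
    optparse
Config/testthat/edition: 3
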