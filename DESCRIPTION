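Package: delayprop
Title: Temporal Backpropagation with Joint Synaptic Weight and Delay
    Learning for Spiking Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulation and supervised training of multi-layer feed-forward
    spiking neural networks of Spike Response Model (SRM) neurons in which
    every synapse carries both a learnable weight and a learnable
    transmission delay.  Gradients of a temporal mean-squared-error loss are
    backpropagated through first-spike times, with a bounded capped-Gaussian
    surrogate replacing the explosion-prone linearization of spike time with
    respect to membrane voltage.  Includes population and latency spike
    encoders, time-to-first-spike decoding, seeded synthetic benchmark
    generators, a finite-difference gradient checker, and a command-line
    runner for reproducible experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
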