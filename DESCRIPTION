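Package: sbsnet
Title: Spike-by-Spike Neural Networks with Error Backpropagation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and supervised training of Spike-by-Spike (SbS)
    networks, in which populations of stochastically firing neurons perform
    generative inference on their spike input and simulated time advances one
    exchanged spike at a time. Provides the multiplicative latent-variable
    dynamic for a single inference population, construction of deep
    feed-forward architectures (dense, convolutional, and competition-based
    pooling layers built from the same population primitive), an error
    backpropagation learning rule with time-retarded latent variables and a
    normalized multiplicative weight update, and a mini-batch optimizer with
    bias-corrected gradient smoothing, divergence-modulated learning rates,
    and dropout by latent-variable initialization. Includes exact Boolean
    benchmark tasks (XOR, 4-bit parity), a synthetic bar-image task for
    convolutional architectures, and a reader for IDX (ubyte) image datasets.
    The per-spike simulation kernel is implemented in C++.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
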