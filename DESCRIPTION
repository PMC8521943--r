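Package: hearscene
Title: Privacy-Preserving Sparse Gammatone Coding, Acoustic Scene
    Classification and Remote Audiometry Simulation for Connected Hearing
    Devices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the computational pipeline of connected hearing
    devices: sparse encoding of audio segments by matching pursuit over a
    unit-norm Gammatone dictionary (a privacy-preserving alternative to
    log-mel features), rasterisation of sparse codes into spikegram
    features, a slim convolutional neural network for 14-class acoustic
    scene classification with a repeated train/test evaluation protocol,
    a deterministic synthetic acoustic-scene corpus generator emulating
    the three-group scene taxonomy of hearing-aid research corpora, and a
    pure-tone audiometry simulator comparing clinical and app-based
    threshold measurement paradigms.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
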