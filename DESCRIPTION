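Package: hetsnn
Title: Heterogeneous Spiking Neural Networks: Simulation, Mean-Field
    Analysis, and Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of all-to-all coupled Izhikevich
    spiking networks with Lorentzian-distributed heterogeneity in external
    drive, recurrent coupling gain, and the partial post-spike reset.
    Includes a four-dimensional mean-field reduction with fixed-point
    continuation, Hopf detection and dynamical-regime classification;
    reservoir-computing experiments with a ridge/recursive-least-squares
    readout; FORCE training of the spiking network with static-gain and
    feedback-gain hyperparameters; a surrogate-gradient stage for
    event-stream classification; and generators for all synthetic inputs
    (target signals, drive pulses, event-stream datasets).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    yaml,
    tools,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
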