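Package: evacnn
Title: Cellular-Automaton Evacuation Simulation and Convolutional
    Inference of Behavioural Rationality
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates room evacuation with a replicator-dynamics cellular
    automaton on a square lattice, in which the weight placed on the exit
    direction (the rational parameter alpha) controls how strongly pedestrians
    press towards the exit, and a mean-field crowd rule models
    bounded-rational herding.  Stacks of binary occupancy snapshots from the
    simulator are turned into labelled multi-channel samples, and a small
    convolutional regression network (implemented in RcppArmadillo) is fitted
    to recover alpha or the initial density from the snapshots, including
    transfer of a rationally-trained model to crowd-rule data to quantify the
    deviation from optimal behaviour.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    graphics,
    grDevices,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
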