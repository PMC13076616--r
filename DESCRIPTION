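Package: emdevolve
Title: Evolving Elementary Motion Detection Circuits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis toolkit for elementary motion detection
    circuits. Generates parametric visual stimuli (moving bars, drifting
    gratings, one-dimensional contrast noise, variable-velocity bars) on a
    two-dimensional arena, drives populations of presynaptic cells with
    Gaussian center-surround receptive fields, first-order release kinetics
    with readily-releasable-pool adaptation and short-term plasticity, and
    integrates their conductances in a two-input linear detector, a passive
    multicompartment cable model on procedurally generated dendritic arbors,
    or a spiking soma. A genetic algorithm with elitist selection evolves
    circuit parameter sets toward direction selectivity, and analysis
    utilities quantify directional tuning (vector-sum direction selectivity
    index), classify evolved solutions into computational primitives
    (Hassenstein-Reichardt, anti-Hassenstein-Reichardt, amplitude, temporal
    alignment; Barlow-Levick, anti-Barlow-Levick, pause-in-inhibition, tuned
    inhibition), measure robustness to velocity noise, and map space-time
    receptive fields from one-dimensional noise stimulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
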