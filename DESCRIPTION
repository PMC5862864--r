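Package: neurodyn
Title: Equation-Based Modeling and Batch Simulation of Neural Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A scriptable toolbox for building and simulating dynamical-systems
    models of neurons and neural networks. Models are written as plain-text
    equations (parameters, functions, ODEs with initial conditions, and
    conditional state resets) or assembled from reusable mechanism objects
    (ion currents, synapses, inputs) that are composed into populations and
    networks through namespaces and linker substitution. The flattened model
    is integrated with fixed-step Euler or Runge-Kutta methods (or delegated
    to an adaptive solver), with per-step conditional updates, spike
    detection by upward threshold crossings, and optional generation of a
    standalone solver script. Parameter sweeps expand into simulation
    batches with deterministic per-simulation seeds, self-describing study
    directories, and analysis hooks for firing rates, power spectra, and
    coherence.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    graphics,
    jsonlite,
    Matrix,
    parallel,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
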