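Package: burstscape
Title: Simulation and Current-Share Visualization of Bursting Neuron Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for building and dissecting degenerate bursting neuron
    models of the crustacean stomatogastric ganglion. Implements a
    single-compartment conductance-based model with eight ionic currents and
    dynamic intracellular calcium, a fixed-step Runge-Kutta integrator,
    threshold-based burst metrics (spike detection, burst segmentation, duty
    cycle, inter-spike-interval distributions), landscape objective functions
    for bursting and tonic-spiking targets, a seedable genetic algorithm for
    conductance search, currentscapes (time-resolved stacked shares of each
    ionic current), and probability-distribution ridge maps of the membrane
    potential and current shares under graded conductance decrements and
    injected-current scans.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    graphics,
    grDevices,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
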