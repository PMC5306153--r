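Package: spineml
Title: Layered Declarative Neural Network Models with Procedural
    Connectivity and a Reference Simulator
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building, validating, serializing and simulating
    layered declarative models of point-neuron networks in a SpineML-style
    XML dialect.  The model is split into three layers: components (reusable
    hybrid dynamical systems with regimes, transitions and typed ports),
    networks (populations, projections with connectivity/weight-update/
    postsynapse synapses, and generic inputs) and experiments (inputs,
    loggers and property overrides).  A procedural 3D layout engine places
    neurons by per-iteration equation evaluation with seeded randomness and
    minimum-distance enforcement; pluggable generator scripts derive
    explicit connection lists from coordinates and are persisted together
    with their generation recipe.  A fixed-step forward-Euler reference
    simulator integrates component dynamics, routes events and impulses
    through delay queues and services loggers.  Shipped fixtures include a
    channel-based basal-ganglia action-selection network of rate-coded
    leaky integrators, its conversion to a spiking leaky integrate-and-fire
    version, and a striatal-like random-cube microcircuit; analysis helpers
    provide Gaussian-kernel firing-rate estimation and selection detection.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    xml2,
    stats,
    utils,
    tools,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
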