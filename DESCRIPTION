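Package: hhnet
Title: Synchronization and Noise Robustness of Coupled Hodgkin-Huxley
    Neuron Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Simulates networks of conductance-based Hodgkin-Huxley neurons
    coupled by electrical (gap-junction) synapses or by delayed chemical
    synapses of the Hansel and Rabinovich threshold type, on ring and
    hub-augmented Newman-Watts small-world topologies.  Provides seeded
    stimulus generators (square wave, sine wave, additive Gaussian white
    noise), a fixed-step fourth-order Runge-Kutta delay-capable network
    integrator with a compiled core, and post-simulation metrics: spike
    detection, first-spike latency and pairwise Pearson correlation of
    membrane-potential traces, assembled into per-synapse synchrony tables
    across a stimulus-by-topology experiment grid.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
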