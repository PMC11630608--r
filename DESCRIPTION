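Package: beliefnet
Title: Qualitative Belief-Network Prediction for Signed Interaction Webs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds and interrogates qualitative signed interaction networks
    (directed edges with integer strengths from -4 to 4) using an iterative
    probabilistic belief-propagation scheme with signal-loss prevention.
    Given a scenario of known changes to some nodes, the engine predicts the
    direction and relative magnitude of change for every other node, with
    optional bootstrap confidence intervals from random edge perturbation,
    edge-sensitivity rankings, stepwise press/pulse time-series dynamics,
    and network diagrams. Includes a synthetic network and scenario
    generator, CSV readers and writers for the three input dialects, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    ggplot2,
    optparse,
    utils,
    stats,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
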