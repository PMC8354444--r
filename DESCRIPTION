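Package: mbplast
Title: Meta-Learned Models of Dopamine-Gated Plasticity in the Mushroom Body
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates the recurrent output circuitry of the Drosophila
    mushroom body (output neurons, dopamine neurons and feedback neurons)
    with timing-dependent, dopamine-gated plasticity of Kenyon-cell inputs,
    and meta-learns the circuit parameters by backpropagation through the
    plastic dynamics. Provides trial generators for classical conditioning,
    continual learning, internal-state tracking and odor-plume navigation,
    a hand-derived gradient engine for the unrolled dynamics, and population
    analyses of simulated dopamine-neuron activity (clustering, principal
    components, response correlations, weight distributions and velocity
    cross-correlations).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
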