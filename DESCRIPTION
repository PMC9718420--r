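Package: eiplast
Title: Nonlinear Inhibitory Plasticity in Rate-Based Excitatory-Inhibitory Circuits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and closed-form analysis of interacting excitatory and
    inhibitory synaptic plasticity in threshold-linear rate circuits. Implements
    a nonlinear inhibitory plasticity rule in which inhibitory-to-excitatory
    synapses change with the same sign as excitatory synapses, together with the
    classical linear rule, metaplastic (sliding) LTD/LTP thresholds, line-attractor
    and separatrix phase-plane theory, stability conditions and eigenvalues,
    excitatory-to-inhibitory weight ratios, input-perturbation and varying-drive
    experiments, and disinhibition-gated receptive-field formation in multi-input
    feedforward and recurrent circuits.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests: optparse, testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
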