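Package: wtadyn
Title: Dynamics of Asymmetric Winner-Take-All Threshold-Linear Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and dynamical-systems analysis of soft winner-take-all
    (sWTA) recurrent networks of linear threshold neurons with asymmetric
    excitatory-inhibitory coupling. Provides network builders (chain WTA
    motifs, random grid assemblies), a compiled Euler integrator with noisy
    and state-conditional input protocols, enumeration and classification of
    activation subspaces into permitted and forbidden classes via effective
    Jacobians, Gaussian-divergence transition hierarchies, a Helmholtz-style
    split of subspace dynamics into gradient and rotational components,
    ensemble state-entropy curves, transition graphs, and steering
    experiments, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
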