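Package: bcpnnseq
Title: Sequence Learning in Modular Attractor Networks with
    Bayesian-Hebbian Plasticity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates a hypercolumnar attractor network of rate units with
    per-hypercolumn winner-take-all competition and intrinsic adaptation, and
    trains its connectivity with the BCPNN (Bayesian Confidence Propagation
    Neural Network) learning rule driven by asymmetric synaptic traces.
    Sequences presented as timed clamping protocols are learned as asymmetric
    log-odds weight matrices; recall tempo is controlled analytically through
    the adaptation gain; tools are provided for persistence-time theory,
    success-rate statistics under additive noise with Wald confidence
    intervals, stochastic bisection for noise-robustness thresholds, and
    overlapping-sequence disambiguation experiments.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
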