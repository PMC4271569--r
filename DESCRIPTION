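Package: ssgrn
Title: S-System Gene Regulatory Network Inference with Sensitivity-Guided
    Hybrid GA-PSO Optimization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reverse engineering of gene regulatory networks from time-series
    expression profiles using the decoupled S-system power-law ODE model.
    Parameters of each per-gene sub-problem are estimated with a hybrid
    genetic-algorithm / particle-swarm optimizer that is coupled, in an
    iterative loop, with a modified multi-parameter sensitivity analysis
    (m-MPSA): sampled candidate solutions are split into acceptable and
    unacceptable sets by a fitness threshold, cumulative-frequency curves of
    the two sets are compared by Pearson correlation to rank parameter
    sensitivity, and sensitive parameters are confined to tight search bounds
    around the current best solution. Includes the two standard artificial
    benchmark networks (5 and 10 genes), fixed-step RK4 simulation, structure
    scoring against prior topologies, and delimited-text/JSON/SIF input and
    output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr,
    yaml
Config/testthat/edition: 3
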