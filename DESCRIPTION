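Package: lapnet
Title: Reinforcement-Learned Linear Assignment for Multi-Target Cell Tracking
Version: 0.1.0
Authors@R: person("lapnet", "maintainers", email = "lapnet@example.org",
    role = c("aut", "cre"))
Description: Solves the linear assignment problem (LAP) with a small residual
    convolutional policy network trained by REINFORCE, and applies it to
    frame-to-frame data association in multi-target (cell) tracking.  Provides
    the event-aware augmented cost matrix in which track loss and track birth
    become ordinary assignment decisions, exact Hungarian-type and brute-force
    solvers used as oracles and for reward computation, a constant-velocity
    Kalman tracker, seeded simulators for maximum-weight-matching instances
    and a multi-target crossing scenario, and evaluation metrics (optimality
    ratio, OSPA-T, identity switches).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
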