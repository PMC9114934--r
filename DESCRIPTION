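Package: motorsynergy
Title: Spatio-Temporal Motor Synergy Extraction and Generalization for
    Multi-Directional Arm Reaching
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how motor-synergy repertoires generalize to
    new reaching targets on a simulated seven-degree-of-freedom torque-controlled
    arm. Provides a self-contained rigid-body arm simulator, a multi-directional
    reciprocating reaching task, proximal policy optimization (PPO) for training
    reaching policies, a training-free surrogate expert based on minimum-jerk
    references with computed-torque control, spatio-temporal synergy extraction
    by non-negative matrix factorization of signed joint-torque trajectories,
    and generalization to targets on new planes by combining synergy repertoires
    and optimizing their activation magnitudes with the covariance matrix
    adaptation evolution strategy (CMA-ES).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils,
    tibble,
    ggplot2,
    rlang
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
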