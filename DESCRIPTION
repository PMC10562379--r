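Package: membandit
Title: Memory Sampling and Reinforcement Learning in a Restless Three-Armed Bandit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for a restless three-armed
    bandit task with trial-unique mnemonic content. Provides the task
    environment (decaying Gaussian random-walk payoffs with reflecting
    bounds and rotating targets, room/context schedules, memory-probe
    placement), a hybrid choice model combining recency-weighted memory
    sampling with temporal-difference reinforcement learning and a
    three-term softmax policy, maximum a-posteriori fitting with truncated
    priors and a random-restart rule, a probe-triggered memory-intrusion
    logistic regression with evoked-context-reward regressors and serial
    Gram-Schmidt orthogonalization of a gist regressor, Mnemonic
    Similarity Task lure-discrimination scoring, Kendall tau-b correlation
    utilities with the sine mapping to linear correlations, and a
    synthetic lifespan-cohort generator so that parameter recovery and the
    target-versus-gist context dissociation can be exercised end to end
    without participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    glmnet,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
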