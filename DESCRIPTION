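Package: polcomp
Title: Policy Compression Models of Capacity-Limited Reinforcement Learning
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation, fitting, and analysis tools for capacity-limited
    reinforcement learning under the policy compression framework. Provides
    task environments for three-state/three-action instrumental learning with
    state-frequency, action-redundancy and time-pressure manipulations; the
    optimal reward-complexity frontier via a Blahut-Arimoto algorithm;
    cost-sensitive actor-critic process models with trial-wise response-time
    generation; Standard RL and RLWM comparison models with Linear Ballistic
    Accumulator choice/RT likelihoods; joint maximum-likelihood fitting of
    choice and response time with BIC model comparison; parameter- and
    model-recovery studies; and behavioral metrics including a Bayesian
    (Hutter) estimator of empirical policy complexity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
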