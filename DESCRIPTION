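Package: rmlsim
Title: Discrete Reinforcement Meta-Learner for Cortical-Brainstem Control Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a four-module actor-critic agent in which two cortical
    decision systems (action selection and catecholamine boosting) recurrently
    control two brainstem neuromodulatory modules: a dopaminergic module that
    computes reward teaching signals with controllable gain, and a
    noradrenergic module that discounts action costs and sets adaptive
    learning rates through an approximate Kalman filter. Includes generators
    for multi-regime bandit tasks, effort-based choice tasks and higher-order
    conditioning chains, lesion manipulations, protocol runners for
    multi-subject cohorts, cost-benefit boost sweeps, and reproducible
    trial-level trace logging.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
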