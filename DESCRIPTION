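Package: ghostrl
Title: Dual-System Reinforcement Learning with Retrospective State Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation, model fitting and model comparison for a dual-outcome
    restless-bandit task in which a hidden fair coin (a "ghost") selects which
    member of a chosen object-pair is executed. Implements hybrid
    model-based/model-free Q-learning agents with separate learning rates for
    standard, ghost-nominated and ghost-rejected choices, room-value and
    object-value model-based systems, eligibility-trace pure model-free
    variants, multi-start maximum-likelihood fitting with a compiled
    likelihood core, bootstrap generalized likelihood-ratio tests (individual
    and group), parametric bootstrap cross-fitting for non-nested model
    classification, Benjamini-Hochberg FDR control, and the model-agnostic
    behavioral regression and contrast analyses that diagnose model-free
    credit assignment guided by model-based retrospective inference.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    lme4,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
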