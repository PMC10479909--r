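Package: choicerl
Title: Reinforcement-Learning Models of Choice Seeking in a Two-Stage Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and model-based analysis of human choice seeking in a
    two-stage decision task, where subjects first decide between a free choice
    opportunity and a computer-forced action before performing a rewarded
    second-stage action. Provides generators for three task variants
    (graded reward probability, relative-value trade-off, and action-outcome
    incoherence), a factorial family of temporal-difference learning agents
    combining optimistic, pessimistic and SARSA future-value targets with an
    intrinsic free-choice bonus, stickiness and a static choice bias,
    trial-level maximum a posteriori fitting with a fast compiled likelihood,
    BIC Schwarz-weight model comparison, parameter- and model-recovery
    pipelines, and descriptive behavioral summaries (choice preference,
    conditional stay probabilities, reward-repetition odds and preference
    reversal points).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
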