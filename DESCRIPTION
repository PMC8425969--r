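Package: pavbias
Title: Pavlovian Bias and Outcome Controllability in the Orthogonalized
    Go/NoGo Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of the orthogonalized Go/NoGo
    reinforcement-learning task with a yoked low-controllability
    manipulation. Provides the task engine (schedules, probabilistic
    feedback, Go-cost, card-specific yoked outcome replay), a
    Rescorla-Wagner/Q-learning hybrid choice model with a Pavlovian bias
    parameter usable both as a generative agent and as a likelihood,
    hierarchical Bayesian estimation of its parameters with block,
    controllability and stimulation effects at the group level, and the
    model-free behavioral statistics used with this paradigm: Pavlovian
    performance index, accuracy and percent-Go tables, mixed
    between-within ANOVA with partial eta squared, and Cohen's d with
    bias-corrected and accelerated bootstrap confidence intervals.
    Includes a synthetic-cohort generator with known ground truth for
    parameter- and effect-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    boot,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
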