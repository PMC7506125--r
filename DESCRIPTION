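Package: surpriseRL
Title: Surprise-Sensitive Utility Models for Reinforcement Learning of
    Choice Behaviour
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and fitting toolkit for reinforcement-learning
    models of trial-and-error choice, centred on the surprise-sensitive
    utility model in which the absolute reward prediction error
    (surprise) reduces the subjective value of an outcome,
    S(t) = r(t) - d*|r(t) - Q(t)|. Implements the three standard
    comparison models (Q-learning, nonlinear-utility Q-learning, and
    risk-sensitive Q-learning with asymmetric learning rates), the
    risky probabilistic learning task, Bernoulli and Gaussian bandit
    tasks, behavioural summaries (sure-choice probability, reward-
    history-conditioned stay probability, choice rates), maximum a
    posteriori fitting with Laplace-approximated model evidence, and
    random-effects Bayesian model selection (exceedance and protected
    exceedance probabilities, Bayes omnibus risk), plus synthetic-cohort
    generators for parameter- and model-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
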