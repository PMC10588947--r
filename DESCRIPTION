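Package: lvbandit
Title: Latent Value Updating of Unchosen Actions in Multi-Armed Bandit Tasks
Version: 0.1.0
Authors@R:
    person("Avery", "Quinn", email = "avery.quinn@example.org", role = c("aut", "cre"))
Description: Simulation, model fitting and model comparison for studying how
    people assign credit to actions they considered but did not take. Provides
    a generator for a four-armed restless bandit task with drifting reward
    probabilities and interleaved win/loss blocks; four Q-learning observers
    (a chosen-only baseline, two double-updating variants that invert the
    outcome or the prediction error for the unchosen option, and a
    select-reject learner that keeps separate value ledgers for choosing a
    card and for rejecting it); hierarchical Bayesian parameter estimation
    with an adaptive MCMC sampler; leave-one-block-out expected log predictive
    density model comparison; the model-independent lagged-trial logistic
    regression analysis of choices of previously unchosen options; and
    parameter-recovery, model-recovery and signature-reproduction experiment
    recipes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
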