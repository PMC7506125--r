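# Shared fixtures, built in code.

# A hand-written session with full control over trials.
manual_session <- function(offered, choice, reward,
                           trial_type = rep("choice", length(choice)),
                           lr_decay = FALSE, q0 = 0, subject_id = "manual") {
  trials <- data.frame(trial = seq_along(choice), trial_type = trial_type,
                       offered = offered, choice = choice, reward = reward,
                       stringsAsFactors = FALSE)
  surpriseRL:::new_session(trials, subject_id, lr_decay = lr_decay, q0 = q0)
}

# Session in which the agent always picks arm1 of a two-armed bandit,
# with a prescribed reward sequence.
always_arm1_session <- function(rewards) {
  manual_session(offered = rep("arm1;arm2", length(rewards)),
                 choice = rep("arm1", length(rewards)),
                 reward = rewards)
}

# Random parameter draws inside each model's box, for property tests.
random_params <- function(model) {
  switch(model,
    qlearning = model_params("qlearning", alpha = runif(1),
                             beta = runif(1, 0, 2)),
    surprise = model_params("surprise", alpha = runif(1),
                            beta = runif(1, 0, 2), d = runif(1, -1, 1)),
    risk_sensitive = model_params("risk_sensitive", alpha_pos = runif(1),
                                  alpha_neg = runif(1),
                                  beta = runif(1, 0, 2)),
    utility = model_params("utility", alpha = runif(1),
                           beta = runif(1, 0, 2), a = runif(1, 1, 30))
  )
}

small_bandit <- function(n_trials = 40, p = c(0.7, 0.3), r = c(1, 1)) {
  build_bernoulli_bandit(p = p, r = r, n_trials = n_trials)
}
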