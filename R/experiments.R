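# Per-agent sure-choice fraction on the {sure20, risky} trials.
.sure_frac_one <- function(s, sure = "sure20", risky = "risky") {
  sel <- s$trial_type == "choice" & .offer_is_pair(s$offered, sure, risky)
  if (!any(sel)) return(NA_real_)
  mean(s$choice[sel] == sure)
}

#' Sure-choice probability over a d x alpha grid
#'
#' Simulates surprise-model agents on the risky probabilistic learning
#' task for every combination of learning rate and surprise decay rate,
#' and summarises the probability of choosing the sure option on the
#' \{sure 20 vs risky\} trials. Each agent receives its own seeded
#' trial-order permutation of the 234-trial task.
#'
#' @param alphas Learning rates to sweep.
#' @param ds Surprise decay rates to sweep.
#' @param beta Inverse temperature. The default 0.05 (cent-valued
#'   rewards, so a 20-cent value gap drives the choice odds by e) puts
#'   sure-choice probabilities in the observed behavioural range while
#'   leaving room for the surprise effect at every learning rate.
#' @param n_agents Agents per grid cell.
#' @param seed Master seed.
#' @return Data frame with columns `alpha`, `d`, `mean_sure`, `se`.
#' @export
experiment_fig2_sweep <- function(alphas = c(0.2, 0.5, 0.8),
                                  ds = seq(0, 1, by = 0.25),
                                  beta = 0.05, n_agents = 1000, seed = 1) {
  grid <- expand.grid(alpha = alphas, d = ds)
  out <- lapply(seq_len(nrow(grid)), function(g) {
    params <- model_params("surprise", alpha = grid$alpha[g], beta = beta,
                           d = grid$d[g])
    cell_seed <- derive_seed(seed, g)
    fr <- vapply(seq_len(n_agents), function(i) {
      task <- build_risk_task(derive_seed(cell_seed, n_agents + i))
      s <- simulate_agent(params, task, seed = derive_seed(cell_seed, i))
      .sure_frac_one(s)
    }, numeric(1))
    data.frame(alpha = grid$alpha[g], d = grid$d[g],
               mean_sure = mean(fr), se = sd(fr) / sqrt(n_agents))
  })
  do.call(rbind, out)
}

#' Sure-choice probability of all four models on the risky task
#'
#' Simulates a group of agents per model on the risky task and returns
#' each model's mean probability of choosing the sure option. Parameter
#' sets are supplied per model (named list of [model_params()]).
#'
#' @param param_list Named list of `rl_params`, one per model to run.
#' @param n_agents Agents per model.
#' @param seed Master seed.
#' @return Data frame with columns `model`, `mean_sure`, `se`.
#' @export
experiment_fig1_models <- function(param_list, n_agents = 1000, seed = 1) {
  out <- lapply(seq_along(param_list), function(k) {
    params <- param_list[[k]]
    mseed <- derive_seed(seed, k)
    fr <- vapply(seq_len(n_agents), function(i) {
      task <- build_risk_task(derive_seed(mseed, n_agents + i))
      s <- simulate_agent(params, task, seed = derive_seed(mseed, i))
      .sure_frac_one(s)
    }, numeric(1))
    data.frame(model = names(param_list)[k] %||% params$model,
               mean_sure = mean(fr), se = sd(fr) / sqrt(n_agents))
  })
  do.call(rbind, out)
}

#' Stay probability of Q-learning vs the surprise model on a bandit
#'
#' Simulates both models on a two-armed Bernoulli bandit with constant
#' learning rates and tabulates the reward-history-conditioned stay
#' probability for each.
#'
#' @param alpha,beta Shared learning rate and inverse temperature.
#' @param d Surprise decay rate of the surprise model.
#' @param p,r Per-arm reward probabilities and magnitudes.
#' @param n_trials Trials per agent.
#' @param n_agents Agents per model.
#' @param seed Master seed.
#' @return Data frame: the [stay_probability_table()] of each model,
#'   with a `model` column.
#' @export
experiment_fig4_stay <- function(alpha = 0.3, beta = 2, d = 0.5,
                                 p = c(0.8, 0.2), r = c(1, 1),
                                 n_trials = 500, n_agents = 1000,
                                 seed = 1) {
  task <- build_bernoulli_bandit(p = p, r = r, n_trials = n_trials)
  models <- list(
    qlearning = model_params("qlearning", alpha = alpha, beta = beta),
    surprise = model_params("surprise", alpha = alpha, beta = beta, d = d)
  )
  out <- lapply(names(models), function(m) {
    sessions <- simulate_agents(models[[m]], task, n_agents,
                                seed = derive_seed(seed, match(m, names(models))))
    cbind(model = m, stay_probability_table(sessions))
  })
  do.call(rbind, out)
}

#' Stay probability across surprise decay rates
#'
#' Simulates the surprise model on the two-armed Bernoulli bandit for
#' each value of `d` and tabulates stay probabilities.
#'
#' @param ds Surprise decay rates to sweep.
#' @inheritParams experiment_fig4_stay
#' @return Data frame of stay tables with a `d` column.
#' @export
experiment_fig5_dsweep <- function(ds = c(0.1, 0.5, 0.9), alpha = 0.3,
                                   beta = 2, p = c(0.8, 0.2), r = c(1, 1),
                                   n_trials = 500, n_agents = 1000,
                                   seed = 1) {
  task <- build_bernoulli_bandit(p = p, r = r, n_trials = n_trials)
  out <- lapply(seq_along(ds), function(k) {
    params <- model_params("surprise", alpha = alpha, beta = beta,
                           d = ds[k])
    sessions <- simulate_agents(params, task, n_agents,
                                seed = derive_seed(seed, k))
    cbind(d = ds[k], stay_probability_table(sessions))
  })
  do.call(rbind, out)
}

#' Choice of the larger-reward safe option: QL vs surprise
#'
#' Two safe-option bandits (both arms rewarded with probability 0.9)
#' differing only in the magnitude of the smaller reward: a small gap
#' (1 vs 0.8) and a large gap (1 vs 0.3). Returns each model's rate of
#' choosing the larger-reward arm in each variant.
#'
#' With a small gap, surprise shrinks both arms' values almost
#' uniformly, which acts like a lower inverse temperature and makes
#' the surprise model pick the better arm less often. With a large
#' gap the surprise model can pick the better arm *more* often — but
#' only in the early-learning regime: the rarely chosen low-value arm
#' retains a stale, optimistic value, and the large prediction error
#' on sampling it is amplified by surprise, repelling the agent faster
#' than plain Q-learning. At steady state no such reversal exists
#' (per-option surprise rescales both arms' stationary values by the
#' common factor (1-d)/(1-d(2p-1)), strictly shrinking the value gap),
#' so the defaults put the simulation in that transient regime:
#' optimistic initial values at the large reward magnitude, a slow
#' constant learning rate, and a short session.
#'
#' @param alpha,beta,d Model parameters.
#' @param r_small Smaller-arm magnitudes of the two variants.
#' @param p Common reward probability.
#' @param q0 Initial action value (default 1, the large reward).
#' @param n_trials Trials per agent (default 100; the reversal is an
#'   early-learning phenomenon).
#' @param n_agents Agents per model and variant.
#' @param seed Master seed.
#' @return Data frame with columns `variant`, `model`, `rate_big_arm`,
#'   `se`.
#' @export
experiment_fs5_safe <- function(alpha = 0.05, beta = 2, d = 0.5,
                                r_small = c(0.8, 0.3), p = 0.9, q0 = 1,
                                n_trials = 100, n_agents = 1000,
                                seed = 1) {
  models <- list(
    qlearning = model_params("qlearning", alpha = alpha, beta = beta),
    surprise = model_params("surprise", alpha = alpha, beta = beta, d = d)
  )
  out <- list()
  for (v in seq_along(r_small)) {
    task <- build_bernoulli_bandit(p = c(p, p), r = c(1, r_small[v]),
                                   n_trials = n_trials)
    for (m in names(models)) {
      sessions <- simulate_agents(
        models[[m]], task, n_agents, q0 = q0,
        seed = derive_seed(seed, v * 10L + match(m, names(models))))
      cr <- choice_rate(sessions, "arm1")
      out[[length(out) + 1L]] <- data.frame(
        variant = sprintf("r=1 vs r=%g", r_small[v]), model = m,
        rate_big_arm = cr$mean, se = cr$se, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
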