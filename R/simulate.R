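# Internal constructor for a session object: one agent's ordered trial
# records plus bookkeeping attributes.
new_session <- function(trials, subject_id, lr_decay = TRUE, q0 = 0,
                        task = NULL) {
  structure(trials,
            class = c("rl_session", "data.frame"),
            subject_id = subject_id,
            lr_decay = lr_decay,
            q0 = q0,
            task = task)
}

#' @export
print.rl_session <- function(x, ...) {
  cat("<rl_session> subject ", attr(x, "subject_id"), ": ", nrow(x),
      " trials (", sum(x$trial_type == "choice"), " choice)\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat("... ", nrow(x) - 5, " more trials\n")
  invisible(x)
}

#' Simulate one agent on a task
#'
#' Walks the task's trial templates in order. On choice trials the
#' agent samples an option from its softmax choice probabilities; on
#' forced trials it takes the single offered stimulus. The outcome is
#' drawn from the chosen stimulus's payoff distribution (scaled by the
#' task's `reward_scale`) and the agent's state is advanced by the
#' model's learning rule. Fully reproducible for a fixed seed.
#'
#' @param params An [model_params()] object.
#' @param task An `rl_task`.
#' @param seed Integer seed.
#' @param decay Use the exposure-decayed learning rate? `NULL`
#'   (default) takes the task's `lr_decay` setting.
#' @param clip Cap effective learning rates at 1?
#' @param q0 Initial action value for every stimulus; `NULL` (default)
#'   takes the task's `q0` setting.
#' @param subject_id Label stored with the session.
#' @return An `rl_session`: a data frame with columns `trial`
#'   (1-based), `trial_type`, `offered` (semicolon-joined ids),
#'   `choice` and `reward`.
#' @examples
#' task <- build_bernoulli_bandit(p = c(0.8, 0.2), r = c(1, 1), n_trials = 50)
#' sess <- simulate_agent(model_params("qlearning", alpha = 0.3, beta = 2),
#'                        task, seed = 1)
#' @export
simulate_agent <- function(params, task, seed, decay = NULL, clip = FALSE,
                           q0 = NULL, subject_id = "agent1") {
  stopifnot(inherits(params, "rl_params"), inherits(task, "rl_task"))
  if (is.null(decay)) decay <- task$lr_decay
  if (is.null(q0)) q0 <- task$q0 %||% 0
  ct <- compile_task(task)
  n <- length(ct$offered)
  model <- params$model
  beta <- params$beta
  choice_idx <- integer(n)
  reward <- numeric(n)
  withr::with_seed(seed, {
    q <- rep_len(q0, length(ct$ids))
    t_s <- integer(length(ct$ids))
    for (t in seq_len(n)) {
      off <- ct$offered[[t]]
      if (ct$is_choice[t]) {
        z <- beta * q[off]
        z <- exp(z - max(z))
        ch <- off[sample.int(length(off), 1L, prob = z)]
      } else {
        ch <- off[1L]
      }
      k <- ct$kind[ch]
      r <- if (k == 1L) {
        ct$fixed_value[ch]
      } else if (k == 2L) {
        b <- ct$bern[[ch]]
        b$values[findInterval(runif(1L), b$cum) + 1L]
      } else {
        rnorm(1L, ct$gmean[ch], ct$gsd[ch])
      }
      r <- r * ct$reward_scale
      choice_idx[t] <- ch
      reward[t] <- r
      q[ch] <- .q_step(model, q[ch], r, t_s[ch], params, decay, clip)
      t_s[ch] <- t_s[ch] + 1L
    }
  })
  trials <- data.frame(
    trial = seq_len(n),
    trial_type = task$trials$trial_type,
    offered = task$trials$offered,
    choice = ct$ids[choice_idx],
    reward = reward,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  new_session(trials, subject_id, lr_decay = decay, q0 = q0, task = task)
}

#' Simulate a group of identical agents
#'
#' Runs `n_agents` independent agents with the same parameters. `task`
#' may be a fixed `rl_task` (all agents see the same trial order) or a
#' function `function(seed)` returning a task, in which case each agent
#' gets its own seeded task (e.g. a fresh trial-order permutation of
#' the risky task). Per-agent seeds are derived from `seed` by a
#' counter scheme.
#'
#' @param params An `rl_params`.
#' @param task An `rl_task`, or a function of a seed returning one.
#' @param n_agents Number of agents.
#' @param seed Master seed.
#' @inheritParams simulate_agent
#' @return List of `rl_session` objects.
#' @export
simulate_agents <- function(params, task, n_agents, seed, decay = NULL,
                            clip = FALSE, q0 = NULL) {
  lapply(seq_len(n_agents), function(i) {
    s_i <- derive_seed(seed, i)
    task_i <- if (is.function(task)) task(derive_seed(seed, i + n_agents)) else task
    simulate_agent(params, task_i, seed = s_i, decay = decay, clip = clip,
                   q0 = q0, subject_id = sprintf("agent%03d", i))
  })
}

# Set-equality between a semicolon-joined offer string and a pair.
.offer_is_pair <- function(offered, a, b) {
  vapply(strsplit(offered, ";", fixed = TRUE), function(o) {
    length(o) == 2L && all(sort(o) == sort(c(a, b)))
  }, logical(1))
}

#' Probability of choosing the sure option
#'
#' For each session, the fraction of choice trials offering exactly the
#' \{sure, risky\} pair on which the sure option was chosen — the risk-
#' aversion index of the risky probabilistic learning task (the 30
#' "risk" trials of the 234-trial preset).
#'
#' @param sessions An `rl_session` or list of them.
#' @param sure,risky Stimulus ids of the sure and risky options.
#' @return List with `per_subject` (named numeric), `mean`, and `se`
#'   (standard error of the mean across subjects).
#' @export
prob_sure_choice <- function(sessions, sure = "sure20", risky = "risky") {
  sessions <- as_session_list(sessions)
  per <- vapply(sessions, function(s) {
    sel <- s$trial_type == "choice" & .offer_is_pair(s$offered, sure, risky)
    if (!any(sel)) return(NA_real_)
    mean(s$choice[sel] == sure)
  }, numeric(1))
  if (all(is.na(per))) {
    stop("no choice trials offering {", sure, ", ", risky, "} found")
  }
  names(per) <- vapply(sessions, attr, character(1), "subject_id")
  m <- mean(per, na.rm = TRUE)
  n_ok <- sum(!is.na(per))
  se <- if (n_ok > 1) sd(per, na.rm = TRUE) / sqrt(n_ok) else NA_real_
  list(per_subject = per, mean = m, se = se)
}

as_session_list <- function(sessions) {
  if (inherits(sessions, "rl_session")) return(list(sessions))
  stopifnot(is.list(sessions), length(sessions) > 0L)
  ok <- vapply(sessions, inherits, logical(1), "rl_session")
  if (!all(ok)) stop("sessions must be rl_session objects")
  sessions
}

#' Stay probability conditioned on reward history
#'
#' For every interior trial t (2 <= t <= n-1) of an all-choice bandit
#' session, classifies the trial by whether the previous and current
#' outcomes were rewarded (strictly positive), and scores a "stay" when
#' the choice at t+1 repeats the choice at t. Conditioning uses only
#' the reward values at t-1 and t; no requirement is placed on the
#' choice at t-1. Returns per-condition means and between-subject
#' standard errors.
#'
#' @param sessions An `rl_session` or list of them; each needs at least
#'   3 trials and binary (0/positive) outcomes.
#' @return Data frame with columns `prev_rewarded`, `cur_rewarded`,
#'   `stay_mean`, `stay_se`, `n_obs` (pooled trial count per
#'   condition).
#' @export
stay_probability_table <- function(sessions) {
  sessions <- as_session_list(sessions)
  conds <- expand.grid(prev_rewarded = c(FALSE, TRUE),
                       cur_rewarded = c(FALSE, TRUE))
  per_agent <- vapply(sessions, function(s) {
    n <- nrow(s)
    if (n < 3L) stop("stay probability needs at least 3 trials")
    t <- 2:(n - 1L)
    prev <- s$reward[t - 1L] > 0
    cur <- s$reward[t] > 0
    stay <- s$choice[t + 1L] == s$choice[t]
    vapply(seq_len(4L), function(k) {
      sel <- prev == conds$prev_rewarded[k] & cur == conds$cur_rewarded[k]
      if (!any(sel)) NA_real_ else mean(stay[sel])
    }, numeric(1))
  }, numeric(4))
  n_obs <- vapply(seq_len(4L), function(k) {
    sum(vapply(sessions, function(s) {
      t <- 2:(nrow(s) - 1L)
      sum((s$reward[t - 1L] > 0) == conds$prev_rewarded[k] &
            (s$reward[t] > 0) == conds$cur_rewarded[k])
    }, numeric(1)))
  }, numeric(1))
  per_agent <- matrix(per_agent, nrow = 4L)
  m <- apply(per_agent, 1L, mean, na.rm = TRUE)
  se <- apply(per_agent, 1L, function(v) {
    v <- v[!is.na(v)]
    if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_
  })
  data.frame(conds, stay_mean = m, stay_se = se, n_obs = n_obs)
}

#' Choice rate of a stimulus
#'
#' Mean over agents of the per-agent fraction of choice trials, among
#' those on which `stimulus` was offered, where it was chosen.
#'
#' @param sessions An `rl_session` or list of them.
#' @param stimulus Stimulus id.
#' @return List with `per_subject`, `mean` and `se`.
#' @export
choice_rate <- function(sessions, stimulus) {
  sessions <- as_session_list(sessions)
  per <- vapply(sessions, function(s) {
    off <- strsplit(s$offered, ";", fixed = TRUE)
    sel <- s$trial_type == "choice" &
      vapply(off, function(o) stimulus %in% o, logical(1))
    if (!any(sel)) return(NA_real_)
    mean(s$choice[sel] == stimulus)
  }, numeric(1))
  if (all(is.na(per))) stop("stimulus '", stimulus, "' never offered")
  names(per) <- vapply(sessions, attr, character(1), "subject_id")
  n_ok <- sum(!is.na(per))
  list(per_subject = per, mean = mean(per, na.rm = TRUE),
       se = if (n_ok > 1) sd(per, na.rm = TRUE) / sqrt(n_ok) else NA_real_)
}

#' Replay a session under a model, returning the value trajectory
#'
#' Deterministically replays recorded trials (choices and rewards)
#' through a model's learning rule, returning the matrix of action
#' values before each trial (row t = Q at the start of trial t; the
#' final row is the state after the last trial). Useful for comparing
#' learning trajectories across models on identical data.
#'
#' @param params An `rl_params`.
#' @param session An `rl_session`.
#' @param decay Use the exposure-decayed rate? `NULL` takes the
#'   session's stored setting.
#' @param clip Cap effective learning rates at 1?
#' @param q0 Initial action value; `NULL` takes the session's stored
#'   setting.
#' @return Numeric matrix, (n_trials + 1) x n_stimuli.
#' @export
replay_session <- function(params, session, decay = NULL, clip = FALSE,
                           q0 = NULL) {
  stopifnot(inherits(params, "rl_params"), inherits(session, "rl_session"))
  if (is.null(decay)) decay <- attr(session, "lr_decay") %||% TRUE
  if (is.null(q0)) q0 <- attr(session, "q0") %||% 0
  cs <- compile_session(session)
  n <- length(cs$choice)
  q <- rep_len(q0, length(cs$ids))
  t_s <- integer(length(cs$ids))
  out <- matrix(NA_real_, n + 1L, length(cs$ids),
                dimnames = list(NULL, cs$ids))
  for (t in seq_len(n)) {
    out[t, ] <- q
    ch <- cs$choice[t]
    q[ch] <- .q_step(params$model, q[ch], cs$reward[t], t_s[ch], params,
                     decay, clip)
    t_s[ch] <- t_s[ch] + 1L
  }
  out[n + 1L, ] <- q
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Integer-indexed form of a session used by replay and likelihood.
compile_session <- function(session) {
  off <- strsplit(session$offered, ";", fixed = TRUE)
  ids <- sort(unique(unlist(off)))
  choice <- match(session$choice, ids)
  if (anyNA(choice)) stop("session contains choices outside the offer sets")
  offered <- lapply(off, match, table = ids)
  bad <- which(mapply(function(o, c) !(c %in% o), offered, choice))
  if (length(bad) > 0L) {
    stop("choice not among offered stimuli at trial(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  list(ids = ids, offered = offered, choice = choice,
       reward = session$reward,
       is_choice = session$trial_type == "choice")
}
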