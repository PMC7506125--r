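#' Define a stimulus and its payoff distribution
#'
#' A stimulus pays out according to one of three distribution kinds:
#' `"fixed"` (a degenerate payoff `value`), `"bernoulli"` (a discrete
#' mixture over `values` with probabilities `probs`), or `"gaussian"`
#' (`mean` and `sd`).
#'
#' @param id Stimulus identifier (character scalar).
#' @param kind Distribution kind.
#' @param value Payoff for `kind = "fixed"`.
#' @param values,probs Support and probabilities for
#'   `kind = "bernoulli"`; `probs` must sum to 1.
#' @param mean,sd Parameters for `kind = "gaussian"`; `sd >= 0`.
#' @return An object of class `rl_stimulus`.
#' @examples
#' stimulus_spec("risky", "bernoulli", values = c(0, 40), probs = c(0.5, 0.5))
#' @export
stimulus_spec <- function(id, kind = c("fixed", "bernoulli", "gaussian"),
                          value = NULL, values = NULL, probs = NULL,
                          mean = NULL, sd = NULL) {
  kind <- match.arg(kind)
  id <- as.character(id)
  stopifnot(length(id) == 1L, nzchar(id))
  s <- list(id = id, kind = kind)
  if (kind == "fixed") {
    stopifnot(is.numeric(value), length(value) == 1L, is.finite(value))
    s$value <- value
  } else if (kind == "bernoulli") {
    stopifnot(is.numeric(values), is.numeric(probs),
              length(values) == length(probs), all(probs >= 0))
    if (abs(sum(probs) - 1) > 1e-9) stop("probs must sum to 1")
    s$values <- values
    s$probs <- probs
  } else {
    stopifnot(is.numeric(mean), length(mean) == 1L, is.finite(mean))
    if (!is.numeric(sd) || length(sd) != 1L || sd < 0) {
      stop("sd must be a single non-negative number")
    }
    s$mean <- mean
    s$sd <- sd
  }
  structure(s, class = "rl_stimulus")
}

#' Assemble a task specification
#'
#' A task is an ordered list of trial templates over a fixed stimulus
#' set. Forced trials offer exactly one stimulus (the agent experiences
#' its outcome without a choice); choice trials offer two or more.
#'
#' @param stimuli List of [stimulus_spec()] objects.
#' @param trials Data frame with columns `trial_type` (`"choice"` or
#'   `"forced"`) and `offered` (semicolon-joined stimulus ids).
#' @param n_sessions Number of equal session blocks the trials divide
#'   into (bookkeeping only; learning state persists across blocks).
#' @param reward_scale Multiplicative factor applied to every sampled
#'   outcome. The inverse temperature interacts with reward units, so
#'   any fitted `beta` must be reported together with this scale.
#' @param lr_decay Default learning-rate treatment for agents on this
#'   task: `TRUE` applies the exposure-decayed rate.
#' @param q0 Default initial action value for agents on this task, in
#'   the task's (scaled) reward units.
#' @return An object of class `rl_task`.
#' @export
task_spec <- function(stimuli, trials, n_sessions = 1, reward_scale = 1,
                      lr_decay = TRUE, q0 = 0) {
  stopifnot(is.list(stimuli), length(stimuli) > 0L)
  ok <- vapply(stimuli, inherits, logical(1), "rl_stimulus")
  if (!all(ok)) stop("stimuli must be a list of stimulus_spec objects")
  ids <- vapply(stimuli, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate stimulus ids")
  names(stimuli) <- ids
  trials <- as.data.frame(trials, stringsAsFactors = FALSE)
  stopifnot(all(c("trial_type", "offered") %in% names(trials)))
  if (!all(trials$trial_type %in% c("choice", "forced"))) {
    stop("trial_type must be 'choice' or 'forced'")
  }
  offered <- strsplit(trials$offered, ";", fixed = TRUE)
  n_off <- lengths(offered)
  if (any(trials$trial_type == "forced" & n_off != 1L)) {
    stop("forced trials must offer exactly one stimulus")
  }
  if (any(trials$trial_type == "choice" & n_off < 2L)) {
    stop("choice trials must offer at least two stimuli")
  }
  unknown <- setdiff(unique(unlist(offered)), ids)
  if (length(unknown) > 0L) {
    stop("offered stimuli not in the stimulus set: ",
         paste(unknown, collapse = ", "))
  }
  stopifnot(n_sessions >= 1, nrow(trials) %% n_sessions == 0)
  stopifnot(is.numeric(reward_scale), reward_scale > 0)
  stopifnot(is.numeric(q0), length(q0) == 1L, is.finite(q0))
  structure(list(stimuli = stimuli, trials = trials,
                 n_sessions = as.integer(n_sessions),
                 reward_scale = reward_scale,
                 lr_decay = isTRUE(lr_decay), q0 = q0),
            class = "rl_task")
}

#' @export
print.rl_task <- function(x, ...) {
  cat("<rl_task> ", nrow(x$trials), " trials (",
      sum(x$trials$trial_type == "choice"), " choice, ",
      sum(x$trials$trial_type == "forced"), " forced) over ",
      length(x$stimuli), " stimuli, ", x$n_sessions, " session block(s)\n",
      sep = "")
  invisible(x)
}

#' Build the 234-trial risky probabilistic learning task
#'
#' Five stimuli: a sure 40, a sure 20, two sure 0 stimuli (distinct
#' ids, separate values and exposure counts), and a risky stimulus
#' paying 0 or 40 with equal probability. The trial composition is
#' fixed: 30 risk choice trials (sure 20 vs risky), 20 test choice
#' trials for each of the pairs \{40 vs risky\}, \{20 vs 40\},
#' \{0a vs risky\}, \{0a vs 20\}, 20 choice trials between the two 0
#' stimuli, and forced trials (24 each for the 40, 20 and risky
#' stimuli, 16 for each 0 stimulus). The order is one seeded uniform
#' permutation of all 234 templates, cut into three 78-trial session
#' blocks; learning state persists across blocks. Rewards are in cents.
#'
#' Agents on this task start with action values at 20 cents (the risky
#' option's expected value and the middle sure payoff). The decayed
#' learning rate makes the first experienced outcome dominate, so the
#' starting value is quickly washed out for every model — except at the
#' surprise model's degenerate point d = 1, where a zero start with
#' non-negative payoffs would freeze all values at zero (surprise
#' exactly cancels any positive prediction error) and force chance
#' behaviour; a mid-scale start keeps that endpoint informative.
#'
#' @param seed Integer seed for the trial-order permutation.
#' @param reward_scale Multiplicative reward factor (default 1 =
#'   cents); the initial value scales with it.
#' @return An `rl_task` with 234 trials.
#' @export
build_risk_task <- function(seed = 1, reward_scale = 1) {
  stimuli <- list(
    stimulus_spec("sure40", "fixed", value = 40),
    stimulus_spec("sure20", "fixed", value = 20),
    stimulus_spec("zero_a", "fixed", value = 0),
    stimulus_spec("zero_b", "fixed", value = 0),
    stimulus_spec("risky", "bernoulli", values = c(0, 40),
                  probs = c(0.5, 0.5))
  )
  choice_pairs <- c(
    rep("sure20;risky", 30),
    rep("sure40;risky", 20),
    rep("sure20;sure40", 20),
    rep("zero_a;risky", 20),
    rep("zero_a;sure20", 20),
    rep("zero_a;zero_b", 20)
  )
  forced <- c(rep("sure40", 24), rep("sure20", 24), rep("risky", 24),
              rep("zero_a", 16), rep("zero_b", 16))
  trials <- data.frame(
    trial_type = c(rep("choice", length(choice_pairs)),
                   rep("forced", length(forced))),
    offered = c(choice_pairs, forced),
    stringsAsFactors = FALSE
  )
  perm <- withr::with_seed(seed, sample.int(nrow(trials)))
  task_spec(stimuli, trials[perm, , drop = FALSE], n_sessions = 3,
            reward_scale = reward_scale, lr_decay = TRUE,
            q0 = 20 * reward_scale)
}

#' Build a Bernoulli multi-armed bandit task
#'
#' Every trial is a choice among all arms; arm `i` pays `r[i]` with
#' probability `p[i]` and 0 otherwise. The default learning-rate
#' treatment on this task is the constant (non-decayed) rate, matching
#' the plain-rate simulations the task is used for.
#'
#' @param p Per-arm reward probabilities in \[0, 1\].
#' @param r Per-arm reward magnitudes (same length as `p`).
#' @param n_trials Number of trials (>= 1).
#' @param reward_scale Multiplicative reward factor.
#' @param lr_decay Default learning-rate treatment (default `FALSE`).
#' @return An `rl_task`.
#' @examples
#' build_bernoulli_bandit(p = c(0.8, 0.2), r = c(1, 1), n_trials = 500)
#' @export
build_bernoulli_bandit <- function(p, r, n_trials, reward_scale = 1,
                                   lr_decay = FALSE) {
  if (length(p) != length(r)) {
    stop("p and r must have the same length")
  }
  stopifnot(all(p >= 0), all(p <= 1), n_trials >= 1)
  ids <- paste0("arm", seq_along(p))
  stimuli <- lapply(seq_along(p), function(i) {
    if (p[i] == 1) {
      stimulus_spec(ids[i], "fixed", value = r[i])
    } else {
      stimulus_spec(ids[i], "bernoulli", values = c(r[i], 0),
                    probs = c(p[i], 1 - p[i]))
    }
  })
  trials <- data.frame(trial_type = "choice",
                       offered = rep(paste(ids, collapse = ";"), n_trials),
                       stringsAsFactors = FALSE)
  task_spec(stimuli, trials, n_sessions = 1, reward_scale = reward_scale,
            lr_decay = lr_decay)
}

#' Build a Gaussian multi-armed bandit task
#'
#' All arms share a common mean payoff but differ in payoff spread;
#' arm `i` pays `Normal(mean, sds[i])` (not truncated at 0). Every
#' trial is a choice among all arms.
#'
#' @param mean Common mean payoff.
#' @param sds Per-arm standard deviations (>= 0); one arm per entry.
#' @param n_trials Number of trials.
#' @param reward_scale Multiplicative reward factor; outcomes are
#'   sampled in task units and then scaled, so choose a scale that
#'   keeps `beta * Q` in a workable range when fitting.
#' @return An `rl_task`.
#' @export
build_gaussian_bandit <- function(mean, sds, n_trials, reward_scale = 1) {
  if (any(sds < 0)) stop("standard deviations must be non-negative")
  stopifnot(n_trials >= 1)
  ids <- paste0("arm", seq_along(sds))
  stimuli <- lapply(seq_along(sds), function(i) {
    stimulus_spec(ids[i], "gaussian", mean = mean, sd = sds[i])
  })
  trials <- data.frame(trial_type = "choice",
                       offered = rep(paste(ids, collapse = ";"), n_trials),
                       stringsAsFactors = FALSE)
  task_spec(stimuli, trials, n_sessions = 1, reward_scale = reward_scale,
            lr_decay = TRUE)
}

#' Named task presets
#'
#' `"risk234"`: the 234-trial risky probabilistic learning task.
#' `"bandit2"`: two-armed Bernoulli bandit, reward probabilities
#' 0.8 vs 0.2, unit rewards, 500 trials. `"gauss4"`: four-armed
#' Gaussian bandit, mean 250 and standard deviations 0/10/30/70
#' (euros), 200 trials, with a default reward scale of 0.01 so that
#' scaled action values stay commensurate with the inverse-temperature
#' range.
#'
#' @param name Preset name.
#' @param seed Seed for the risk task's trial-order permutation
#'   (ignored by the bandit presets, whose templates are fixed).
#' @return An `rl_task`.
#' @export
task_preset <- function(name = c("risk234", "bandit2", "gauss4"), seed = 1) {
  name <- match.arg(name)
  switch(name,
    risk234 = build_risk_task(seed),
    bandit2 = build_bernoulli_bandit(p = c(0.8, 0.2), r = c(1, 1),
                                     n_trials = 500),
    gauss4  = build_gaussian_bandit(mean = 250, sds = c(0, 10, 30, 70),
                                    n_trials = 200, reward_scale = 0.01)
  )
}

#' Draw one outcome from a stimulus
#'
#' Samples a single payoff from the stimulus's distribution using the
#' current RNG state, multiplied by `reward_scale`.
#'
#' @param stimulus An [stimulus_spec()] object.
#' @param reward_scale Multiplicative factor (default 1).
#' @return A single reward value.
#' @export
sample_outcome <- function(stimulus, reward_scale = 1) {
  stopifnot(inherits(stimulus, "rl_stimulus"))
  x <- switch(stimulus$kind,
    fixed     = stimulus$value,
    bernoulli = stimulus$values[sample.int(length(stimulus$values), 1L,
                                           prob = stimulus$probs)],
    gaussian  = rnorm(1L, stimulus$mean, stimulus$sd)
  )
  x * reward_scale
}

# ---- compiled (integer-indexed) task form used by the hot loops ----

# kinds: 1 fixed, 2 bernoulli, 3 gaussian
compile_task <- function(task) {
  ids <- names(task$stimuli)
  kind <- integer(length(ids))
  fixed_value <- numeric(length(ids))
  bern <- vector("list", length(ids))
  gmean <- numeric(length(ids))
  gsd <- numeric(length(ids))
  for (i in seq_along(ids)) {
    s <- task$stimuli[[i]]
    if (s$kind == "fixed") {
      kind[i] <- 1L
      fixed_value[i] <- s$value
    } else if (s$kind == "bernoulli") {
      kind[i] <- 2L
      bern[[i]] <- list(values = s$values, cum = cumsum(s$probs))
    } else {
      kind[i] <- 3L
      gmean[i] <- s$mean
      gsd[i] <- s$sd
    }
  }
  offered <- lapply(strsplit(task$trials$offered, ";", fixed = TRUE),
                    function(o) match(o, ids))
  list(ids = ids, kind = kind, fixed_value = fixed_value, bern = bern,
       gmean = gmean, gsd = gsd, offered = offered,
       is_choice = task$trials$trial_type == "choice",
       reward_scale = task$reward_scale)
}

#' Serialise a task to JSON
#' @param task An `rl_task`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_task <- function(task, path) {
  stopifnot(inherits(task, "rl_task"))
  obj <- list(
    stimuli = lapply(task$stimuli, function(s) unclass(s)),
    trials = task$trials,
    n_sessions = task$n_sessions,
    reward_scale = task$reward_scale,
    lr_decay = task$lr_decay,
    q0 = task$q0
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a task from JSON
#' @param path File written by [write_task()].
#' @return An `rl_task`.
#' @export
read_task <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = TRUE)
  stimuli <- lapply(obj$stimuli, function(s) {
    do.call(stimulus_spec, s[!vapply(s, is.null, logical(1))])
  })
  task_spec(unname(stimuli), obj$trials, n_sessions = obj$n_sessions,
            reward_scale = obj$reward_scale, lr_decay = obj$lr_decay,
            q0 = obj$q0 %||% 0)
}
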