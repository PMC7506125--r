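MODEL_NAMES <- c("qlearning", "utility", "risk_sensitive", "surprise")

# Parameter boxes shared by constructors, priors and optimizer bounds.
PARAM_BOXES <- list(
  alpha     = c(0, 1),
  alpha_pos = c(0, 1),
  alpha_neg = c(0, 1),
  beta      = c(0, 10),
  d         = c(-1, 1),
  a         = c(1, 30)
)

#' Free parameters of each model
#'
#' Returns the names of the free parameters of a model, in their
#' canonical order: `alpha`, `beta` for Q-learning; `alpha`, `beta`, `a`
#' for the utility model; `alpha_pos`, `alpha_neg`, `beta` for the
#' risk-sensitive model; `alpha`, `beta`, `d` for the surprise model.
#'
#' @param model Model name, one of `"qlearning"`, `"utility"`,
#'   `"risk_sensitive"`, `"surprise"`.
#' @return Character vector of parameter names.
#' @export
model_param_names <- function(model) {
  model <- match.arg(model, MODEL_NAMES)
  switch(model,
    qlearning      = c("alpha", "beta"),
    utility        = c("alpha", "beta", "a"),
    risk_sensitive = c("alpha_pos", "alpha_neg", "beta"),
    surprise       = c("alpha", "beta", "d")
  )
}

#' Construct a validated parameter set for one model
#'
#' Bundles the free parameters of a learning model, checking each against
#' its admissible range: learning rates (`alpha`, `alpha_pos`,
#' `alpha_neg`) in \[0, 1\], inverse temperature `beta` in \[0, 10\],
#' surprise decay rate `d` in \[-1, 1\], utility curvature `a` in
#' \[1, 30\]. Parameters that do not belong to `model` are rejected.
#'
#' @param model Model name (see [model_param_names()]).
#' @param ... Named parameter values.
#' @return An object of class `rl_params`.
#' @examples
#' model_params("surprise", alpha = 0.3, beta = 2, d = 0.5)
#' @export
model_params <- function(model, ...) {
  model <- match.arg(model, MODEL_NAMES)
  vals <- list(...)
  wanted <- model_param_names(model)
  extra <- setdiff(names(vals), wanted)
  if (length(extra) > 0L) {
    stop("parameters not used by the ", model, " model: ",
         paste(extra, collapse = ", "))
  }
  missing <- setdiff(wanted, names(vals))
  if (length(missing) > 0L) {
    stop("missing parameters for the ", model, " model: ",
         paste(missing, collapse = ", "))
  }
  for (nm in wanted) {
    v <- vals[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("parameter '", nm, "' must be a single finite number")
    }
    box <- PARAM_BOXES[[nm]]
    if (v < box[1] || v > box[2]) {
      stop("parameter '", nm, "' = ", v, " outside its range [",
           box[1], ", ", box[2], "]")
    }
  }
  structure(c(list(model = model), vals[wanted]), class = "rl_params")
}

#' @export
print.rl_params <- function(x, ...) {
  nm <- model_param_names(x$model)
  cat("<rl_params> model: ", x$model, "\n  ",
      paste(sprintf("%s = %g", nm, unlist(x[nm])), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Convert a named numeric vector to rl_params
#' @param model Model name.
#' @param theta Named numeric vector with the model's parameters.
#' @return An `rl_params` object.
#' @export
params_from_vector <- function(model, theta) {
  do.call(model_params, c(list(model = model),
                          as.list(theta[model_param_names(model)])))
}

#' Initialise an agent's learning state
#'
#' Creates the per-stimulus action values `Q` and exposure counts `T`
#' (the number of trials on which the consequence of each stimulus has
#' been experienced). Action values start at `q0` (default 0; all task
#' outcomes are non-negative, so this is a pessimistic baseline).
#'
#' @param stimuli Character vector of stimulus identifiers.
#' @param q0 Initial action value (scalar or one per stimulus).
#' @return An object of class `rl_state` with components `Q` and `T`.
#' @export
agent_state <- function(stimuli, q0 = 0) {
  stimuli <- as.character(stimuli)
  if (anyDuplicated(stimuli)) stop("duplicate stimulus ids")
  if (length(stimuli) == 0L) stop("at least one stimulus is required")
  stopifnot(is.numeric(q0), all(is.finite(q0)))
  Q <- rep_len(q0, length(stimuli))
  names(Q) <- stimuli
  T_s <- integer(length(stimuli))
  names(T_s) <- stimuli
  structure(list(Q = Q, T = T_s), class = "rl_state")
}

#' @export
print.rl_state <- function(x, ...) {
  cat("<rl_state>", length(x$Q), "stimuli\n")
  print(rbind(Q = x$Q, T = x$T))
  invisible(x)
}

#' Exposure-decayed effective learning rate
#'
#' The effective learning rate is the base rate plus a decaying bonus,
#' `alpha + 0.5 / (1 + t_s)`, where `t_s` counts how many times the
#' stimulus's outcome has been experienced. The bonus makes early
#' outcomes weigh heavily and decays toward the base rate. With
#' `clip = TRUE` the result is capped at 1 (the update never overshoots
#' the target); by default no cap is applied.
#'
#' @param alpha Base learning rate in \[0, 1\].
#' @param t_s Non-negative integer exposure count (vectorised).
#' @param clip Cap the result at 1?
#' @return Effective learning rate(s).
#' @examples
#' decayed_learning_rate(0.2, 0)  # 0.7
#' decayed_learning_rate(0.5, 9)  # 0.55
#' @export
decayed_learning_rate <- function(alpha, t_s, clip = FALSE) {
  if (!is.numeric(alpha) || any(alpha < 0) || any(alpha > 1)) {
    stop("alpha must lie in [0, 1]")
  }
  if (!is.numeric(t_s) || any(t_s < 0) || any(t_s != floor(t_s))) {
    stop("t_s must be a non-negative integer count")
  }
  out <- alpha + 0.5 / (1 + t_s)
  if (clip) out <- pmin(out, 1)
  out
}

#' Surprise-modulated subjective utility
#'
#' The subjective value of an outcome after discounting by surprise
#' (the absolute prediction error): `S = r - d * |r - Q|`. With `d = 0`
#' or a perfectly predicted outcome (`r = Q`) the utility equals the raw
#' outcome; positive `d` shrinks the value of surprising outcomes.
#'
#' @param r Received outcome (task reward units).
#' @param q Expected value of the chosen option before the outcome.
#' @param d Surprise decay rate in \[-1, 1\].
#' @return Subjective utility (vectorised over `r` and `q`).
#' @examples
#' surprise_utility(40, 20, 0.5)  # 30
#' @export
surprise_utility <- function(r, q, d) {
  if (!all(is.finite(r)) || !all(is.finite(q))) {
    stop("r and q must be finite")
  }
  if (!is.numeric(d) || any(d < -1) || any(d > 1)) {
    stop("d must lie in [-1, 1]")
  }
  r - d * abs(r - q)
}

#' Nonlinear utility of an objective reward
#'
#' The utility model maps the risky task's three objective payoffs to
#' subjective utilities anchored at `U(0) = 0`, `U(20) = 20` and
#' `U(40) = a * 20`; `a = 2` is the linear (risk-neutral) case. For
#' tasks with continuous outcomes the anchors are interpolated by the
#' power law `U(x) = 20 * (x / 20)^log2(a)`, which passes exactly
#' through all three anchors and is extended oddly
#' (`U(-x) = -U(x)`) to negative outcomes. The power-law extension is
#' an extrapolation beyond the discrete payoffs the utility model was
#' defined on; it is only used when `continuous = TRUE`.
#'
#' @param r Objective reward. With `continuous = FALSE` (default) it
#'   must be one of 0, 20, 40.
#' @param a Utility curvature in \[1, 30\].
#' @param continuous Allow arbitrary rewards via the power law?
#' @return Subjective utility (vectorised over `r`).
#' @examples
#' utility_transform(40, a = 5)  # 100
#' @export
utility_transform <- function(r, a, continuous = FALSE) {
  if (!is.numeric(a) || length(a) != 1L || a < 1 || a > 30) {
    stop("a must lie in [1, 30]")
  }
  if (!continuous && !all(r %in% c(0, 20, 40))) {
    stop("discrete utility is defined only for rewards 0, 20, 40; ",
         "set continuous = TRUE for other outcomes")
  }
  sign(r) * 20 * (abs(r) / 20)^log2(a)
}

# Scalar Q update for the chosen stimulus; shared by the public
# update_state() and the compiled simulation/likelihood loops.
# par is a plain list with the model's parameters.
.q_step <- function(model, q, r, t_s, par, decay, clip) {
  bonus <- if (decay) 0.5 / (1 + t_s) else 0
  if (model == "risk_sensitive") {
    delta <- r - q
    base <- if (delta > 0) par$alpha_pos else par$alpha_neg
    lr <- base + bonus
    if (clip) lr <- min(lr, 1)
    if (delta == 0) return(q)
    return(q + lr * delta)
  }
  lr <- par$alpha + bonus
  if (clip) lr <- min(lr, 1)
  target <- switch(model,
    qlearning = r,
    surprise  = r - par$d * abs(r - q),
    utility   = sign(r) * 20 * (abs(r) / 20)^log2(par$a)
  )
  q + lr * (target - q)
}

#' Apply one outcome to the agent's state
#'
#' Updates the chosen stimulus's action value according to the model's
#' learning rule and increments its exposure count; all other stimuli
#' are untouched. The effective learning rate is the exposure-decayed
#' rate from [decayed_learning_rate()] evaluated at the pre-update
#' count (pass `decay = FALSE` for the constant-rate variant used in
#' the simple bandit simulations). Update targets: the raw reward
#' (Q-learning), the surprise-discounted utility (surprise model), the
#' nonlinear utility (utility model); the risk-sensitive model uses the
#' raw reward with `alpha_pos` for positive and `alpha_neg` for
#' negative prediction errors (a zero prediction error leaves the value
#' unchanged under either rate).
#'
#' @param state An `rl_state`.
#' @param params An `rl_params`.
#' @param stimulus Chosen stimulus id (must exist in `state`).
#' @param r Received outcome.
#' @param decay Use the exposure-decayed learning rate? Default `TRUE`.
#' @param clip Cap effective learning rates at 1? Default `FALSE`.
#' @return The updated `rl_state`.
#' @export
update_state <- function(state, params, stimulus, r,
                         decay = TRUE, clip = FALSE) {
  stopifnot(inherits(state, "rl_state"), inherits(params, "rl_params"))
  if (!is.finite(r)) stop("reward must be finite")
  stimulus <- as.character(stimulus)
  if (!stimulus %in% names(state$Q)) {
    stop("unknown stimulus id: ", stimulus)
  }
  state$Q[[stimulus]] <- .q_step(params$model, state$Q[[stimulus]], r,
                                 state$T[[stimulus]], params, decay, clip)
  state$T[[stimulus]] <- state$T[[stimulus]] + 1L
  state
}

# Numerically stable softmax of beta * q.
.softmax <- function(q, beta) {
  z <- beta * q
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

#' Softmax choice probabilities over the offered options
#'
#' Probability of choosing each offered stimulus,
#' `P(i) = exp(beta * Q_i) / sum_j exp(beta * Q_j)`, computed with
#' max-subtraction so large `beta * Q` cannot overflow. `beta = 0`
#' yields the uniform distribution; the result is invariant to adding a
#' constant to every action value.
#'
#' @param state An `rl_state`.
#' @param params An `rl_params` (only `beta` is used).
#' @param offered Character vector of offered stimulus ids (non-empty).
#' @return Named probability vector over `offered` (sums to 1).
#' @export
choice_probabilities <- function(state, params, offered) {
  stopifnot(inherits(state, "rl_state"), inherits(params, "rl_params"))
  offered <- as.character(offered)
  if (length(offered) == 0L) stop("offer set must be non-empty")
  missing <- setdiff(offered, names(state$Q))
  if (length(missing) > 0L) {
    stop("unknown stimulus id(s): ", paste(missing, collapse = ", "))
  }
  p <- .softmax(state$Q[offered], params$beta)
  names(p) <- offered
  p
}
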