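#' Prior specification for MAP fitting
#'
#' Defaults: learning rates (`alpha`, `alpha_pos`, `alpha_neg`) ~
#' Beta(2, 2) on \[0, 1\]; inverse temperature `beta` ~ Gamma(shape 2,
#' scale 3) on \[0, 10\] (mode 3, well inside the box; set
#' `beta_param = "rate"` to read the second Gamma hyperparameter as a
#' rate instead); utility curvature `a` ~ Uniform(1, 30); surprise
#' decay `d` ~ Uniform(-1, 1). Densities are not renormalised for
#' truncation to the boxes: the truncation constant is shared by all
#' models using a given parameter and does not move MAP locations.
#'
#' @param alpha_shape1,alpha_shape2 Beta hyperparameters for learning
#'   rates.
#' @param beta_shape,beta_scale Gamma hyperparameters for `beta`.
#' @param beta_param Interpret `beta_scale` as a `"scale"` (default)
#'   or `"rate"`.
#' @return An object of class `rl_priors`.
#' @export
prior_spec <- function(alpha_shape1 = 2, alpha_shape2 = 2,
                       beta_shape = 2, beta_scale = 3,
                       beta_param = c("scale", "rate")) {
  beta_param <- match.arg(beta_param)
  structure(list(alpha_shape1 = alpha_shape1, alpha_shape2 = alpha_shape2,
                 beta_shape = beta_shape, beta_scale = beta_scale,
                 beta_param = beta_param),
            class = "rl_priors")
}

# Gamma scale honouring the scale/rate switch.
.beta_gamma_scale <- function(priors) {
  if (priors$beta_param == "scale") priors$beta_scale else 1 / priors$beta_scale
}

# Log prior density of one named parameter value.
prior_logdensity <- function(priors, name, value) {
  switch(name,
    alpha = , alpha_pos = , alpha_neg =
      dbeta(value, priors$alpha_shape1, priors$alpha_shape2, log = TRUE),
    beta = dgamma(value, shape = priors$beta_shape,
                  scale = .beta_gamma_scale(priors), log = TRUE),
    a = dunif(value, PARAM_BOXES$a[1], PARAM_BOXES$a[2], log = TRUE),
    d = dunif(value, PARAM_BOXES$d[1], PARAM_BOXES$d[2], log = TRUE),
    stop("no prior defined for parameter '", name, "'")
  )
}

# One random draw from a parameter's prior, truncated to its box
# (beta's Gamma is truncated to [0, 10] by rejection).
prior_draw <- function(priors, name) {
  switch(name,
    alpha = , alpha_pos = , alpha_neg =
      rbeta(1L, priors$alpha_shape1, priors$alpha_shape2),
    beta = {
      repeat {
        x <- rgamma(1L, shape = priors$beta_shape,
                    scale = .beta_gamma_scale(priors))
        if (x <= PARAM_BOXES$beta[2]) break
      }
      x
    },
    a = runif(1L, PARAM_BOXES$a[1], PARAM_BOXES$a[2]),
    d = runif(1L, PARAM_BOXES$d[1], PARAM_BOXES$d[2])
  )
}

# Prior mode used as the deterministic first optimizer start.
prior_mode <- function(priors, name) {
  switch(name,
    alpha = , alpha_pos = , alpha_neg = {
      a <- priors$alpha_shape1; b <- priors$alpha_shape2
      if (a > 1 && b > 1) (a - 1) / (a + b - 2) else 0.5
    },
    beta = {
      s <- .beta_gamma_scale(priors)
      m <- if (priors$beta_shape >= 1) (priors$beta_shape - 1) * s else 0.1
      min(max(m, 0.1), PARAM_BOXES$beta[2] - 0.1)
    },
    a = mean(PARAM_BOXES$a),
    d = 0
  )
}

#' Log likelihood of a recorded session under a model
#'
#' Replays the session in order. Choice trials contribute the log
#' softmax probability of the recorded choice; forced trials contribute
#' no likelihood term. Every trial (forced and choice) drives the
#' learning update with the recorded reward. The replay is
#' side-effect-free and deterministic.
#'
#' @param params An `rl_params`.
#' @param session An `rl_session` (simulated or read from CSV).
#' @param decay Use the exposure-decayed learning rate? `NULL` takes
#'   the session's stored setting (`TRUE` if absent).
#' @param clip Cap effective learning rates at 1?
#' @param q0 Initial action value; `NULL` takes the session's stored
#'   setting (0 if absent).
#' @return Log likelihood (scalar, <= 0).
#' @export
session_log_likelihood <- function(params, session, decay = NULL,
                                   clip = FALSE, q0 = NULL) {
  stopifnot(inherits(params, "rl_params"))
  if (is.null(decay)) decay <- attr(session, "lr_decay") %||% TRUE
  if (is.null(q0)) q0 <- attr(session, "q0") %||% 0
  cs <- if (is.list(session) && !is.null(session$.compiled)) {
    session$.compiled
  } else {
    compile_session(session)
  }
  .loglik_compiled(params$model, unclass(params), cs, decay, clip, q0)
}

# Hot loop shared by session_log_likelihood and map_fit.
.loglik_compiled <- function(model, par, cs, decay, clip, q0) {
  n <- length(cs$choice)
  q <- rep_len(q0, length(cs$ids))
  t_s <- integer(length(cs$ids))
  beta <- par$beta
  ll <- 0
  for (t in seq_len(n)) {
    ch <- cs$choice[t]
    if (cs$is_choice[t]) {
      z <- beta * q[cs$offered[[t]]]
      m <- max(z)
      ll <- ll + beta * q[ch] - m - log(sum(exp(z - m)))
    }
    q[ch] <- .q_step(model, q[ch], cs$reward[t], t_s[ch], par, decay, clip)
    t_s[ch] <- t_s[ch] + 1L
  }
  ll
}

#' Unnormalised log posterior
#'
#' Sum of [session_log_likelihood()] and the log prior densities of the
#' model's parameters. Parameters outside their boxes return `-Inf`.
#'
#' @inheritParams session_log_likelihood
#' @param priors An [prior_spec()] object.
#' @return Log posterior (scalar).
#' @export
log_posterior <- function(params, session, priors = prior_spec(),
                          decay = NULL, clip = FALSE, q0 = NULL) {
  nm <- model_param_names(params$model)
  lp <- 0
  for (p in nm) {
    v <- params[[p]]
    box <- PARAM_BOXES[[p]]
    if (v < box[1] || v > box[2]) return(-Inf)
    lp <- lp + prior_logdensity(priors, p, v)
  }
  if (!is.finite(lp)) return(-Inf)
  lp + session_log_likelihood(params, session, decay = decay, clip = clip,
                              q0 = q0)
}

#' Fit a model to one session by maximum a posteriori estimation
#'
#' Box-constrained maximisation of the log posterior with `L-BFGS-B`
#' from `n_restarts` start points: the prior mode first, then seeded
#' draws from the priors. The best optimum is kept and the Laplace
#' approximation of the log marginal likelihood is attached. If the
#' optimum lies within 1e-4 of a box edge it is nudged 1e-4 inside
#' before the Hessian is evaluated and the fit is flagged
#' (`boundary = TRUE`), since the Laplace formula assumes an interior
#' mode.
#'
#' @param model Model name.
#' @param session An `rl_session`.
#' @param priors An [prior_spec()].
#' @param n_restarts Number of optimizer starts (>= 1, default 10).
#' @param seed Integer seed for the restart draws.
#' @param decay,clip,q0 Passed to the likelihood (see
#'   [session_log_likelihood()]).
#' @return An object of class `rl_fit`: MAP parameters, `log_posterior`,
#'   `log_evidence`, `hessian_logdet`, `n_params`, `converged`,
#'   `boundary`, `n_restarts_used`, and provenance (`priors`, `seed`,
#'   `decay`, `subject_id`).
#' @export
map_fit <- function(model, session, priors = prior_spec(),
                    n_restarts = 10, seed = 1, decay = NULL,
                    clip = FALSE, q0 = NULL) {
  model <- match.arg(model, MODEL_NAMES)
  stopifnot(n_restarts >= 1)
  if (is.null(decay)) decay <- attr(session, "lr_decay") %||% TRUE
  if (is.null(q0)) q0 <- attr(session, "q0") %||% 0
  cs <- compile_session(session)
  nm <- model_param_names(model)
  k <- length(nm)
  lower <- vapply(nm, function(p) PARAM_BOXES[[p]][1], numeric(1))
  upper <- vapply(nm, function(p) PARAM_BOXES[[p]][2], numeric(1))
  # keep the optimizer off box edges where a prior density vanishes
  eps <- 1e-6
  opt_lower <- lower + ifelse(nm %in% c("alpha", "alpha_pos", "alpha_neg",
                                        "beta"), eps, 0)
  opt_upper <- upper - ifelse(nm %in% c("alpha", "alpha_pos", "alpha_neg"),
                              eps, 0)

  negpost <- function(theta) {
    par <- as.list(theta)
    names(par) <- nm
    par$model <- model
    lp <- 0
    for (p in nm) lp <- lp + prior_logdensity(priors, p, par[[p]])
    if (!is.finite(lp)) return(1e10)
    v <- lp + .loglik_compiled(model, par, cs, decay, clip, q0)
    if (!is.finite(v)) return(1e10)
    -v
  }

  starts <- withr::with_seed(seed, {
    s <- matrix(NA_real_, n_restarts, k, dimnames = list(NULL, nm))
    s[1L, ] <- vapply(nm, function(p) prior_mode(priors, p), numeric(1))
    if (n_restarts > 1L) {
      for (i in 2:n_restarts) {
        s[i, ] <- vapply(nm, function(p) prior_draw(priors, p), numeric(1))
      }
    }
    s
  })

  best <- NULL
  n_ok <- 0L
  for (i in seq_len(n_restarts)) {
    fit <- tryCatch(
      optim(pmin(pmax(starts[i, ], opt_lower), opt_upper), negpost,
            method = "L-BFGS-B", lower = opt_lower, upper = opt_upper,
            control = list(maxit = 500)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    n_ok <- n_ok + 1L
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    stop("map_fit: all ", n_restarts, " optimizer restarts failed for ",
         model)
  }
  theta <- best$par
  names(theta) <- nm
  lap <- laplace_evidence(negpost, theta, lower = lower, upper = upper)
  structure(list(
    model = model,
    params_hat = params_from_vector(model, theta),
    theta = theta,
    log_posterior = -best$value,
    log_evidence = lap$log_evidence,
    hessian_logdet = lap$logdet,
    n_params = k,
    converged = best$convergence == 0,
    boundary = lap$nudged,
    regularized = lap$regularized,
    n_restarts_used = n_ok,
    priors = priors,
    seed = seed,
    decay = decay,
    subject_id = attr(session, "subject_id") %||% NA_character_
  ), class = "rl_fit")
}

#' @export
print.rl_fit <- function(x, ...) {
  cat("<rl_fit> ", x$model, " (", x$n_params, " params)\n  MAP: ",
      paste(sprintf("%s = %.4g", names(x$theta), x$theta), collapse = ", "),
      "\n  log posterior ", sprintf("%.3f", x$log_posterior),
      ", Laplace log evidence ", sprintf("%.3f", x$log_evidence),
      if (x$boundary) " [boundary mode]", "\n", sep = "")
  invisible(x)
}

#' Laplace approximation of the log marginal likelihood
#'
#' Given the negative log posterior `negfn` and its minimiser `theta`,
#' approximates `log p(D | M)` by
#' `-negfn(theta) + (k/2) log(2*pi) - 0.5 * log det H`, with `H` the
#' Hessian of `negfn` at `theta` computed by central finite differences
#' (relative step `rel_step` per coordinate). Coordinates within 1e-4
#' of a supplied bound are nudged 1e-4 inside before differentiation.
#' If the Hessian is not positive definite at the base step the step is
#' enlarged (5x, then 25x) — learning rules with absolute-value kinks
#' make the posterior only piecewise smooth, and a wider stencil
#' averages across the kink; if it is still indefinite, a ridge is
#' applied (with a warning) until the Cholesky factorisation succeeds.
#'
#' @param negfn Negative log posterior, a function of a numeric vector.
#' @param theta Location of the posterior mode.
#' @param lower,upper Optional box bounds (recycled).
#' @param rel_step Base relative finite-difference step (default 1e-4).
#' @return List with `log_evidence`, `hessian`, `logdet`, `theta_used`,
#'   `rel_step_used`, `nudged` and `regularized`.
#' @export
laplace_evidence <- function(negfn, theta, lower = -Inf, upper = Inf,
                             rel_step = 1e-4) {
  k <- length(theta)
  lower <- rep_len(lower, k)
  upper <- rep_len(upper, k)
  th <- pmin(pmax(theta, lower + 1e-4), upper - 1e-4)
  nudged <- any(th != theta)
  f0 <- negfn(th)

  fd_hessian <- function(step) {
    h <- step * pmax(abs(th), 1)
    H <- matrix(NA_real_, k, k)
    for (i in seq_len(k)) {
      ei <- replace(numeric(k), i, h[i])
      H[i, i] <- (negfn(th + ei) - 2 * f0 + negfn(th - ei)) / h[i]^2
      if (i > 1L) {
        for (j in seq_len(i - 1L)) {
          ej <- replace(numeric(k), j, h[j])
          H[i, j] <- H[j, i] <-
            (negfn(th + ei + ej) - negfn(th + ei - ej) -
               negfn(th - ei + ej) + negfn(th - ei - ej)) /
            (4 * h[i] * h[j])
        }
      }
    }
    H
  }

  H <- ch <- NULL
  step_used <- rel_step
  for (mult in c(1, 5, 25)) {
    Hm <- fd_hessian(rel_step * mult)
    chm <- tryCatch(chol(Hm), error = function(e) NULL)
    if (mult == 1) H <- Hm
    if (!is.null(chm)) {
      H <- Hm
      ch <- chm
      step_used <- rel_step * mult
      break
    }
  }
  regularized <- FALSE
  if (is.null(ch)) {
    ridge <- 0
    repeat {
      ch <- tryCatch(chol(H + diag(ridge, k)), error = function(e) NULL)
      if (!is.null(ch)) break
      regularized <- TRUE
      ridge <- if (ridge == 0) 1e-8 * max(abs(diag(H)), 1) else ridge * 10
      if (ridge > 1e6) stop("Hessian could not be regularised")
    }
    if (regularized) {
      warning("negative-log-posterior Hessian not positive definite; ",
              "ridge ", signif(ridge, 3), " applied")
    }
  }
  logdet <- 2 * sum(log(diag(ch)))
  list(log_evidence = -f0 + k / 2 * log(2 * pi) - logdet / 2,
       hessian = H, logdet = logdet, theta_used = th,
       rel_step_used = step_used, nudged = nudged,
       regularized = regularized)
}
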