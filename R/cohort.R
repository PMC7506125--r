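#' Specify a synthetic cohort
#'
#' A cohort is `n_subjects` agents of one model, each with parameters
#' drawn from per-parameter sampling distributions, run on a task.
#' Default distributions: uniform over each parameter's box, except the
#' inverse temperature, which is drawn from its Gamma(2, scale 3) prior
#' truncated to \[0, 10\] so that near-zero-temperature (pure-noise)
#' subjects are rare. Supported distribution forms per parameter:
#' `list(kind = "point", value = v)`,
#' `list(kind = "uniform", min = lo, max = hi)`, and
#' `list(kind = "grid", values = v)` (sampled uniformly with
#' replacement).
#'
#' @param n_subjects Number of subjects.
#' @param model Generating model name.
#' @param task An `rl_task`, or a function of a seed returning one
#'   (each subject then gets its own seeded task instance, e.g. a fresh
#'   risky-task trial order).
#' @param seed Master seed; per-subject seeds are derived from it by a
#'   counter scheme so each subject is individually re-runnable.
#' @param param_dists Named list overriding the default sampling
#'   distribution of selected parameters.
#' @return An object of class `rl_cohort_spec`.
#' @examples
#' cohort_spec(16, "surprise", task = function(s) build_risk_task(s),
#'             seed = 7, param_dists = list(
#'               d = list(kind = "uniform", min = 0, max = 1)))
#' @export
cohort_spec <- function(n_subjects, model, task, seed = 1,
                        param_dists = list()) {
  model <- match.arg(model, MODEL_NAMES)
  stopifnot(n_subjects >= 1)
  if (!inherits(task, "rl_task") && !is.function(task)) {
    stop("task must be an rl_task or a function of a seed")
  }
  nm <- model_param_names(model)
  bad <- setdiff(names(param_dists), nm)
  if (length(bad) > 0L) {
    stop("param_dists for parameters not in the ", model, " model: ",
         paste(bad, collapse = ", "))
  }
  structure(list(n_subjects = as.integer(n_subjects), model = model,
                 task = task, seed = seed, param_dists = param_dists),
            class = "rl_cohort_spec")
}

# Draw one subject's value of one parameter under the cohort's
# distributions (defaults when no override is given).
.draw_param <- function(name, dist, priors = prior_spec()) {
  box <- PARAM_BOXES[[name]]
  if (is.null(dist)) {
    if (name == "beta") return(prior_draw(priors, "beta"))
    return(runif(1L, box[1], box[2]))
  }
  v <- switch(dist$kind,
    point = dist$value,
    uniform = runif(1L, dist$min, dist$max),
    grid = dist$values[sample.int(length(dist$values), 1L)],
    stop("unknown parameter distribution kind: ", dist$kind)
  )
  if (v < box[1] || v > box[2]) {
    stop("sampled value for '", name, "' outside its box")
  }
  v
}

#' Generate a synthetic cohort with known parameters
#'
#' Draws each subject's parameters from the cohort's distributions,
#' simulates the subject on the task with a subject-specific derived
#' seed, and returns the sessions together with the ground-truth
#' parameter table (one row per subject, joined 1:1 by `subject_id`).
#'
#' @param spec An [cohort_spec()].
#' @return An object of class `rl_cohort`: list with `sessions` (list
#'   of `rl_session`), `truth` (data frame), and `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "rl_cohort_spec"))
  nm <- model_param_names(spec$model)
  n <- spec$n_subjects
  truth <- withr::with_seed(derive_seed(spec$seed, 0L), {
    rows <- lapply(seq_len(n), function(i) {
      vapply(nm, function(p) .draw_param(p, spec$param_dists[[p]]),
             numeric(1))
    })
    as.data.frame(do.call(rbind, rows))
  })
  truth$subject_id <- sprintf("s%03d", seq_len(n))
  truth <- truth[c("subject_id", nm)]
  sessions <- lapply(seq_len(n), function(i) {
    params <- params_from_vector(spec$model, unlist(truth[i, nm]))
    task_i <- if (is.function(spec$task)) {
      spec$task(derive_seed(spec$seed, n + i))
    } else {
      spec$task
    }
    simulate_agent(params, task_i, seed = derive_seed(spec$seed, i),
                   subject_id = truth$subject_id[i])
  })
  structure(list(sessions = sessions, truth = truth, spec = spec),
            class = "rl_cohort")
}

#' @export
print.rl_cohort <- function(x, ...) {
  cat("<rl_cohort> ", length(x$sessions), " ", x$spec$model,
      " subjects, ", nrow(x$sessions[[1]]), " trials each\n", sep = "")
  invisible(x)
}

#' Parameter-recovery experiment
#'
#' Generates a cohort, fits `fit_model` to every subject by MAP, and
#' tabulates true against estimated parameters with per-parameter
#' Pearson correlations (computed over the parameters shared by the
#' generating and fitting models). Individual fit failures are
#' reported in the table, not fatal.
#'
#' @param spec An [cohort_spec()].
#' @param fit_model Model to fit (default: the generating model).
#' @param priors An [prior_spec()].
#' @param n_restarts Optimizer restarts per subject (default 10).
#' @param fit_seed Seed for the fits.
#' @return List with `table` (one row per subject: truth, estimates,
#'   `log_evidence`, `ok`), `correlations` (named numeric), `cohort`,
#'   and `fits`.
#' @export
recovery_experiment <- function(spec, fit_model = spec$model,
                                priors = prior_spec(), n_restarts = 10,
                                fit_seed = spec$seed + 1L) {
  cohort <- generate_cohort(spec)
  fit_model <- match.arg(fit_model, MODEL_NAMES)
  nm_fit <- model_param_names(fit_model)
  fits <- lapply(seq_along(cohort$sessions), function(i) {
    tryCatch(
      map_fit(fit_model, cohort$sessions[[i]], priors = priors,
              n_restarts = n_restarts, seed = derive_seed(fit_seed, i)),
      error = function(e) e
    )
  })
  est <- t(vapply(fits, function(f) {
    if (inherits(f, "rl_fit")) f$theta else rep(NA_real_, length(nm_fit))
  }, numeric(length(nm_fit))))
  colnames(est) <- paste0(nm_fit, "_hat")
  tab <- cbind(cohort$truth, est)
  tab$log_evidence <- vapply(fits, function(f) {
    if (inherits(f, "rl_fit")) f$log_evidence else NA_real_
  }, numeric(1))
  tab$ok <- vapply(fits, inherits, logical(1), "rl_fit")
  shared <- intersect(model_param_names(spec$model), nm_fit)
  correlations <- vapply(shared, function(p) {
    x <- tab[[p]]
    y <- tab[[paste0(p, "_hat")]]
    keep <- tab$ok & !is.na(y)
    if (sum(keep) < 3L || sd(x[keep]) == 0 || sd(y[keep]) == 0) {
      return(NA_real_)
    }
    cor(x[keep], y[keep])
  }, numeric(1))
  list(table = tab, correlations = correlations, cohort = cohort,
       fits = fits)
}

#' Model-recovery experiment
#'
#' For each generating cohort, fits every candidate model to every
#' subject, assembles the subjects x models log-evidence matrix, runs
#' random-effects model selection, and records which model attains the
#' highest protected exceedance probability.
#'
#' @param specs Named list of [cohort_spec()] objects, one per
#'   generating model (names default to each spec's model).
#' @param fit_models Candidate models to fit (default: all four).
#' @param priors An [prior_spec()].
#' @param n_restarts Optimizer restarts per fit.
#' @param seed Seed for fits and the exceedance Monte Carlo.
#' @param n_samples Monte Carlo draws for exceedance probabilities.
#' @return List with `summary` (data frame: generating model, selected
#'   model, winning pxp), `bms` (per-cohort `rl_bms`), and `evidence`
#'   (per-cohort matrices).
#' @export
model_recovery_experiment <- function(specs, fit_models = MODEL_NAMES,
                                      priors = prior_spec(),
                                      n_restarts = 10, seed = 1,
                                      n_samples = 1e5) {
  stopifnot(is.list(specs), length(specs) >= 1L)
  if (is.null(names(specs)) || any(!nzchar(names(specs)))) {
    names(specs) <- vapply(specs, `[[`, character(1), "model")
  }
  out_bms <- list()
  out_ev <- list()
  rows <- list()
  for (gname in names(specs)) {
    cohort <- generate_cohort(specs[[gname]])
    ev <- matrix(NA_real_, length(cohort$sessions), length(fit_models),
                 dimnames = list(cohort$truth$subject_id, fit_models))
    for (i in seq_along(cohort$sessions)) {
      for (m in fit_models) {
        f <- tryCatch(
          map_fit(m, cohort$sessions[[i]], priors = priors,
                  n_restarts = n_restarts,
                  seed = derive_seed(seed, i * length(fit_models) +
                                       match(m, fit_models))),
          error = function(e) NULL
        )
        if (!is.null(f)) ev[i, m] <- f$log_evidence
      }
    }
    keep <- rowSums(is.na(ev)) == 0L
    res <- bms(ev[keep, , drop = FALSE], n_samples = n_samples,
               seed = derive_seed(seed, match(gname, names(specs))))
    out_bms[[gname]] <- res
    out_ev[[gname]] <- ev
    rows[[gname]] <- data.frame(
      generating = specs[[gname]]$model,
      selected = fit_models[which.max(res$pxp)],
      pxp_win = max(res$pxp),
      n_subjects_used = sum(keep),
      stringsAsFactors = FALSE
    )
  }
  list(summary = do.call(rbind, rows), bms = out_bms, evidence = out_ev)
}
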