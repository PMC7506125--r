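#' Write sessions to CSV
#'
#' Flat UTF-8 CSV with header `subject_id, trial, trial_type, offered,
#' choice, reward`; offer lists are semicolon-joined, trial indices are
#' 1-based per subject.
#'
#' @param sessions An `rl_session` or list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sessions <- function(sessions, path) {
  sessions <- as_session_list(sessions)
  rows <- lapply(sessions, function(s) {
    cbind(subject_id = attr(s, "subject_id"), as.data.frame(s))
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read sessions from CSV
#'
#' Reads the dialect written by [write_sessions()], validating each
#' row: the choice must be among the offered stimuli, rewards must be
#' numeric, forced trials must offer exactly one stimulus, and trial
#' indices must run consecutively from 1 within each subject.
#' Validation errors report the offending data row numbers.
#'
#' @param path CSV file path.
#' @param lr_decay Learning-rate treatment to record on the sessions
#'   (the CSV itself does not carry it); default `TRUE`.
#' @param q0 Initial action value to record on the sessions (default
#'   0; use 20 for risky-task data in cents).
#' @return List of `rl_session` objects, one per subject, in file
#'   order.
#' @export
read_sessions <- function(path, lr_decay = TRUE, q0 = 0) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "trial", "trial_type", "offered", "choice",
            "reward")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("missing column(s): ", paste(miss, collapse = ", "))
  }
  if (!is.numeric(df$reward)) {
    bad <- which(is.na(suppressWarnings(as.numeric(df$reward))))
    stop("non-numeric reward at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  off <- strsplit(df$offered, ";", fixed = TRUE)
  bad <- which(!mapply(function(o, ch) ch %in% o, off, df$choice))
  if (length(bad) > 0L) {
    stop("choice not among offered stimuli at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  bad <- which(df$trial_type == "forced" & lengths(off) != 1L)
  if (length(bad) > 0L) {
    stop("forced trial offering several stimuli at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  split_rows <- split(seq_len(nrow(df)), factor(df$subject_id,
                                                unique(df$subject_id)))
  lapply(names(split_rows), function(sid) {
    idx <- split_rows[[sid]]
    trials <- df[idx, c("trial", "trial_type", "offered", "choice",
                        "reward")]
    if (!identical(as.integer(trials$trial), seq_len(nrow(trials)))) {
      gap <- idx[which(as.integer(trials$trial) !=
                         seq_len(nrow(trials)))[1]]
      stop("trial indices of subject '", sid,
           "' not consecutive from 1 (first problem at row ", gap, ")")
    }
    rownames(trials) <- NULL
    new_session(trials, sid, lr_decay = lr_decay, q0 = q0)
  })
}

#' Write a subjects x models evidence matrix to CSV
#' @param evidence Numeric matrix with model column names; row names
#'   (or a `subject_id` attribute) label subjects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_evidence <- function(evidence, path) {
  evidence <- as.matrix(evidence)
  df <- data.frame(subject_id = rownames(evidence) %||%
                     sprintf("s%03d", seq_len(nrow(evidence))),
                   evidence, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a subjects x models evidence matrix from CSV
#' @param path CSV written by [write_evidence()] (first column
#'   `subject_id`, one column per model).
#' @return Numeric matrix with subject row names.
#' @export
read_evidence <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "subject_id") {
    stop("first column must be 'subject_id'")
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("evidence values must be numeric")
  rownames(m) <- df$subject_id
  m
}

#' Serialise fit results to JSON
#'
#' One record per fit with the MAP estimates, log posterior, Laplace
#' log evidence, convergence flags, and provenance (priors, seed,
#' learning-rate treatment).
#'
#' @param fits An `rl_fit` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fits <- function(fits, path) {
  if (inherits(fits, "rl_fit")) fits <- list(fits)
  recs <- lapply(fits, function(f) {
    list(subject_id = f$subject_id, model = f$model,
         params = as.list(f$theta), log_posterior = f$log_posterior,
         log_evidence = f$log_evidence,
         hessian_logdet = f$hessian_logdet, n_params = f$n_params,
         converged = f$converged, boundary = f$boundary,
         n_restarts_used = f$n_restarts_used, seed = f$seed,
         decay = f$decay, priors = unclass(f$priors))
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Serialise a BMS result to JSON
#' @param x An `rl_bms`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bms <- function(x, path) {
  stopifnot(inherits(x, "rl_bms"))
  obj <- list(dirichlet_alpha = as.list(x$dirichlet_alpha),
              expected_freq = as.list(x$expected_freq),
              xp = as.list(x$xp), bor = x$bor, pxp = as.list(x$pxp),
              free_energy = x$free_energy, f0 = x$f0,
              alpha0 = x$alpha0, n_subjects = x$n_subjects)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
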