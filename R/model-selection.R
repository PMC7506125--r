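#' Variational Dirichlet estimation of population model frequencies
#'
#' Random-effects model selection treats the model generating each
#' subject's data as a draw from unknown population frequencies with a
#' symmetric Dirichlet prior (`alpha0` per model). The variational
#' fixed point alternates subject-level responsibilities
#' `g_nk ~ exp(l_nk + psi(alpha_k) - psi(sum alpha))` (normalised per
#' subject) with Dirichlet count updates
#' `alpha_k = alpha0 + sum_n g_nk`, iterating until the largest change
#' in `alpha` falls below `tol`. The converged variational free energy
#' of this alternative hypothesis (unequal frequencies) is returned for
#' use by [bayes_omnibus_risk()].
#'
#' @param log_evidence Numeric matrix, subjects x models, of log
#'   marginal likelihoods (nats). Column names label the models.
#' @param alpha0 Prior Dirichlet count per model (> 0; default 1).
#' @param tol Convergence tolerance on `max |delta alpha|`.
#' @param max_iter Iteration cap.
#' @return List with `alpha` (posterior Dirichlet counts), `g`
#'   (subjects x models responsibilities), `expected_freq`
#'   (`alpha / sum(alpha)`), `free_energy`, and `iterations`.
#' @export
vb_dirichlet <- function(log_evidence, alpha0 = 1, tol = 1e-6,
                         max_iter = 1000) {
  log_evidence <- as.matrix(log_evidence)
  stopifnot(is.numeric(log_evidence), all(is.finite(log_evidence)),
            ncol(log_evidence) >= 2L, nrow(log_evidence) >= 1L,
            alpha0 > 0)
  n <- nrow(log_evidence)
  K <- ncol(log_evidence)
  alpha <- rep(alpha0, K)
  g <- matrix(1 / K, n, K)
  for (it in seq_len(max_iter)) {
    lg <- sweep(log_evidence, 2L, digamma(alpha) - digamma(sum(alpha)), "+")
    lg <- lg - apply(lg, 1L, max)
    g <- exp(lg)
    g <- g / rowSums(g)
    alpha_new <- alpha0 + colSums(g)
    delta <- max(abs(alpha_new - alpha))
    alpha <- alpha_new
    if (delta < tol) {
      names(alpha) <- colnames(log_evidence)
      return(list(alpha = alpha, g = g,
                  expected_freq = alpha / sum(alpha),
                  free_energy = .vb_free_energy(log_evidence, g, alpha,
                                                alpha0),
                  iterations = it))
    }
  }
  stop("vb_dirichlet did not converge in ", max_iter,
       " iterations (last max |delta alpha| = ", signif(delta, 4), ")")
}

# Variational free energy (ELBO) of the Dirichlet-multinomial model:
# expected log joint plus entropies, i.e. E[log p(y|m)] + E[log p(m|r)]
# - KL(q(r) || p(r)) + H[q(m)].
.vb_free_energy <- function(log_evidence, g, alpha, alpha0) {
  K <- length(alpha)
  elogr <- digamma(alpha) - digamma(sum(alpha))
  kl_dir <- lgamma(sum(alpha)) - sum(lgamma(alpha)) -
    lgamma(K * alpha0) + K * lgamma(alpha0) +
    sum((alpha - alpha0) * elogr)
  ent_g <- -sum(g[g > 0] * log(g[g > 0]))
  sum(g * log_evidence) + sum(sweep(g, 2L, elogr, "*")) - kl_dir + ent_g
}

#' Exceedance probabilities of a Dirichlet posterior
#'
#' Probability, under `Dirichlet(alpha)`, that each model's population
#' frequency exceeds every other model's. Estimated by Monte Carlo
#' (normalised Gamma draws); for two models the exact Beta tail
#' `P(p1 > 1/2) = 1 - pbeta(0.5, alpha1, alpha2)` is available via
#' `exact_k2 = TRUE`.
#'
#' @param alpha Positive Dirichlet counts (length >= 2).
#' @param n_samples Monte Carlo draws (default 1e6).
#' @param seed Integer seed for the draws.
#' @param exact_k2 Use the closed form when `length(alpha) == 2`?
#' @return Probability vector summing to 1.
#' @export
exceedance_prob <- function(alpha, n_samples = 1e6, seed = 1,
                            exact_k2 = FALSE) {
  stopifnot(all(alpha > 0), length(alpha) >= 2L)
  K <- length(alpha)
  if (exact_k2 && K == 2L) {
    p1 <- 1 - pbeta(0.5, alpha[1], alpha[2])
    xp <- c(p1, 1 - p1)
  } else {
    xp <- withr::with_seed(seed, {
      counts <- integer(K)
      # draw in blocks to bound memory at ~8 MB per column
      block <- 1e5L
      done <- 0L
      while (done < n_samples) {
        m <- min(block, n_samples - done)
        draws <- matrix(rgamma(m * K, shape = rep(alpha, each = m)), m, K)
        win <- max.col(draws, ties.method = "first")
        counts <- counts + tabulate(win, nbins = K)
        done <- done + m
      }
      counts / n_samples
    })
  }
  names(xp) <- names(alpha)
  xp
}

#' Bayes omnibus risk
#'
#' Posterior probability of the null hypothesis that all models are
#' equally frequent in the population, `BOR = 1 / (1 + exp(F1 - F0))`,
#' where `F0` is the log evidence of the fixed uniform-frequency null,
#' `sum_n log((1/K) sum_k exp(l_nk))`, and `F1` the variational free
#' energy of the random-effects alternative from [vb_dirichlet()].
#'
#' @param log_evidence Subjects x models log-evidence matrix.
#' @param vb Converged output of [vb_dirichlet()] on the same matrix.
#' @return Scalar in (0, 1).
#' @export
bayes_omnibus_risk <- function(log_evidence, vb) {
  log_evidence <- as.matrix(log_evidence)
  K <- ncol(log_evidence)
  f0 <- sum(apply(log_evidence, 1L, logsumexp) - log(K))
  stats::plogis(f0 - vb$free_energy)
}

#' Protected exceedance probabilities
#'
#' Shrinks exceedance probabilities toward chance by the probability
#' that observed differences arose under equal frequencies:
#' `pxp_k = (1 - bor) * xp_k + bor / K`.
#'
#' @param xp Exceedance probability vector (sums to 1).
#' @param bor Bayes omnibus risk in \[0, 1\].
#' @return Probability vector summing to 1.
#' @export
protected_xp <- function(xp, bor) {
  stopifnot(abs(sum(xp) - 1) < 1e-6, bor >= 0, bor <= 1)
  (1 - bor) * xp + bor / length(xp)
}

#' Random-effects Bayesian model selection
#'
#' Full pipeline from a subjects x models log-evidence matrix:
#' variational Dirichlet frequencies, exceedance probabilities, Bayes
#' omnibus risk and protected exceedance probabilities.
#'
#' @inheritParams vb_dirichlet
#' @inheritParams exceedance_prob
#' @return An object of class `rl_bms`: list with `dirichlet_alpha`,
#'   `expected_freq`, `xp`, `bor`, `pxp`, `g`, `free_energy`, `f0`.
#' @examples
#' ev <- matrix(c(0, -3, 0.5, -2), 2, 2,
#'              dimnames = list(NULL, c("m1", "m2")))
#' bms(ev, n_samples = 1e4)
#' @export
bms <- function(log_evidence, alpha0 = 1, n_samples = 1e6, seed = 1,
                exact_k2 = FALSE, tol = 1e-6, max_iter = 1000) {
  log_evidence <- as.matrix(log_evidence)
  vb <- vb_dirichlet(log_evidence, alpha0 = alpha0, tol = tol,
                     max_iter = max_iter)
  xp <- exceedance_prob(vb$alpha, n_samples = n_samples, seed = seed,
                        exact_k2 = exact_k2)
  bor <- bayes_omnibus_risk(log_evidence, vb)
  K <- ncol(log_evidence)
  f0 <- sum(apply(log_evidence, 1L, logsumexp) - log(K))
  structure(list(dirichlet_alpha = vb$alpha,
                 expected_freq = vb$expected_freq,
                 xp = xp, bor = bor, pxp = protected_xp(xp, bor),
                 g = vb$g, free_energy = vb$free_energy, f0 = f0,
                 alpha0 = alpha0, n_subjects = nrow(log_evidence)),
            class = "rl_bms")
}

#' @export
print.rl_bms <- function(x, ...) {
  cat("<rl_bms> ", x$n_subjects, " subjects, ",
      length(x$dirichlet_alpha), " models; BOR = ",
      sprintf("%.3f", x$bor), "\n", sep = "")
  print(round(rbind(alpha = x$dirichlet_alpha,
                    expected_freq = x$expected_freq,
                    xp = x$xp, pxp = x$pxp), 4))
  invisible(x)
}

#' One-sample t-test on per-subject parameter estimates
#'
#' Classical one-sample t-test of per-subject estimates against a
#' reference value (e.g. testing whether the fitted surprise decay
#' rate is positive across subjects). Degenerate zero-variance input
#' yields `t = 0` when the common value equals the reference and a
#' flagged infinite `t` otherwise.
#'
#' @param values Numeric vector of per-subject estimates (length >= 2).
#' @param null Reference value (default 0).
#' @return List with `t`, `df`, `p` (two-sided), `mean`, and
#'   `zero_variance` flag.
#' @export
one_sample_t <- function(values, null = 0) {
  stopifnot(is.numeric(values), length(values) >= 2L,
            all(is.finite(values)))
  n <- length(values)
  m <- mean(values)
  s <- sd(values)
  if (s == 0) {
    t_stat <- if (m == null) 0 else Inf * sign(m - null)
    return(list(t = t_stat, df = n - 1L,
                p = if (m == null) 1 else 0,
                mean = m, zero_variance = TRUE))
  }
  tt <- stats::t.test(values, mu = null)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean = m, zero_variance = FALSE)
}
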