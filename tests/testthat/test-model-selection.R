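test_that("variational Dirichlet counts follow the evidence structure", {
  # identical evidences: perfect symmetry
  ev <- matrix(-10, 12, 4, dimnames = list(NULL, paste0("m", 1:4)))
  vb <- vb_dirichlet(ev)
  expect_equal(unname(vb$alpha), rep(1 + 12 / 4, 4))
  expect_true(all(abs(vb$g - 0.25) < 1e-12))
  # a dominant model absorbs every subject
  ev2 <- matrix(0, 10, 3)
  ev2[, 2] <- 50
  vb2 <- vb_dirichlet(ev2)
  expect_equal(unname(vb2$alpha), c(1, 11, 1), tolerance = 1e-6)
  expect_true(all(vb2$g[, 2] > 1 - 1e-12))
  # one subject, two equal evidences: the single fixed point by hand
  vb3 <- vb_dirichlet(matrix(c(0, 0), 1, 2))
  expect_equal(unname(vb3$g[1, ]), c(0.5, 0.5))
  expect_equal(unname(vb3$alpha), c(1.5, 1.5))
})

test_that("exceedance probabilities match the K=2 Beta tail", {
  xp <- exceedance_prob(c(3, 1), n_samples = 2e5, seed = 1)
  expect_equal(unname(xp[1]), 0.875, tolerance = 3 * sqrt(0.875 * 0.125 / 2e5) + 1e-3)
  expect_equal(sum(xp), 1)
  # exact path
  expect_equal(unname(exceedance_prob(c(3, 1), exact_k2 = TRUE)),
               c(1 - pbeta(0.5, 3, 1), pbeta(0.5, 3, 1)))
  # symmetry and dominance limits
  xs <- exceedance_prob(c(2, 2, 2), n_samples = 2e5, seed = 2)
  expect_true(all(abs(xs - 1 / 3) < 0.01))
  xd <- exceedance_prob(c(1000, 1), n_samples = 1e4, seed = 3)
  expect_equal(unname(xd), c(1, 0))
  # property: random alpha pairs agree with the closed form within MC error
  withr::with_seed(11, {
    for (i in 1:10) {
      a <- runif(2, 0.5, 20)
      n <- 1e5
      mc <- exceedance_prob(a, n_samples = n, seed = 100 + i)
      ex <- 1 - pbeta(0.5, a[1], a[2])
      se <- sqrt(max(ex * (1 - ex), 1e-6) / n)
      expect_lt(abs(mc[1] - ex), 3 * se + 1e-4)
    }
  })
})

test_that("Bayes omnibus risk separates null and alternative regimes", {
  # symmetric evidences: no case against equal frequencies
  ev <- matrix(0, 16, 4)
  vb <- vb_dirichlet(ev)
  bor <- bayes_omnibus_risk(ev, vb)
  expect_gt(bor, 0.5)
  # the alternative's free energy never beats F0 under exact symmetry
  f0 <- sum(apply(ev, 1, surpriseRL:::logsumexp) - log(4))
  expect_lt(vb$free_energy, f0)
  # a 20-nat dominant model makes the null untenable
  ev2 <- matrix(0, 16, 4)
  ev2[, 3] <- 20
  bor2 <- bayes_omnibus_risk(ev2, vb_dirichlet(ev2))
  expect_lt(bor2, 1e-4)
  # logistic midpoint when the free energies tie
  expect_equal(bayes_omnibus_risk(ev, list(free_energy = f0)), 0.5)
})

test_that("protected exceedance blends toward uniform by the omnibus risk", {
  expect_equal(protected_xp(c(0.9, 0.1), 0), c(0.9, 0.1))
  expect_equal(protected_xp(c(0.9, 0.1), 1), c(0.5, 0.5))
  expect_equal(protected_xp(c(0.9, 0.1), 0.2), c(0.82, 0.18))
  withr::with_seed(3, {
    for (i in 1:10) {
      xp <- as.vector(prop.table(runif(4)))
      bor <- runif(1)
      pxp <- protected_xp(xp, bor)
      expect_equal(sum(pxp), 1)
      expect_equal(order(pxp), order(xp))
    }
  })
})

test_that("bms pipeline satisfies its identities", {
  withr::with_seed(8, {
    ev <- matrix(rnorm(20 * 3, sd = 3), 20, 3,
                 dimnames = list(NULL, c("a", "b", "c")))
    res <- bms(ev, n_samples = 1e5)
    expect_equal(sum(res$expected_freq), 1)
    expect_equal(sum(res$xp), 1)
    expect_equal(sum(res$pxp), 1, tolerance = 1e-9)
    expect_equal(unname(res$pxp),
                 unname((1 - res$bor) * res$xp + res$bor / 3))
  })
})

test_that("one-sample t-test matches the closed form and flags degeneracy", {
  r <- one_sample_t(c(1, 2, 3), null = 0)
  expect_equal(r$t, sqrt(3) * 2, tolerance = 1e-12)
  expect_equal(r$df, 2)
  expect_equal(one_sample_t(c(-2, -1, 1, 2), null = 0)$t, 0)
  z <- one_sample_t(c(4, 4, 4), null = 4)
  expect_equal(z$t, 0)
  expect_true(z$zero_variance)
  z2 <- one_sample_t(c(4, 4, 4), null = 0)
  expect_equal(z2$t, Inf)
})

test_that("evidence favours the generating model class on average", {
  # Q-learning data: the extra parameter of the 3-parameter models buys
  # no fit, so the Laplace evidence should not prefer them
  spec <- cohort_spec(30, "qlearning", task = small_bandit(120), seed = 55)
  cohort <- generate_cohort(spec)
  ev <- sapply(c("qlearning", "surprise"), function(m) {
    vapply(seq_along(cohort$sessions), function(i) {
      map_fit(m, cohort$sessions[[i]], n_restarts = 3,
              seed = 700 + i)$log_evidence
    }, numeric(1))
  })
  diffs <- ev[, "qlearning"] - ev[, "surprise"]
  expect_gt(mean(diffs), -2 * sd(diffs) / sqrt(length(diffs)))
})

test_that("model selection recovers the generating model", {
  mk <- function(m, extra = list()) {
    cohort_spec(8, m, task = function(s) build_risk_task(s), seed = 202,
                param_dists = extra)
  }
  specs <- list(
    qlearning = mk("qlearning"),
    utility = mk("utility"),
    risk_sensitive = mk("risk_sensitive"),
    surprise = mk("surprise",
                  list(d = list(kind = "uniform", min = 0.5, max = 1)))
  )
  res <- suppressWarnings(
    model_recovery_experiment(specs, n_restarts = 3, seed = 9,
                              n_samples = 1e5))
  hits <- sum(res$summary$generating == res$summary$selected)
  expect_gte(hits, 3)
  # injected symmetric evidences declare no winner
  sym <- bms(matrix(5, 10, 4), n_samples = 1e4)
  expect_true(all(abs(sym$pxp - 0.25) < 0.01))
})
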