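test_that("decayed learning rate follows alpha + 0.5/(1+T) and caps only when asked", {
  expect_equal(decayed_learning_rate(0.2, 0), 0.7)
  expect_equal(decayed_learning_rate(0.5, 9), 0.55)
  expect_equal(decayed_learning_rate(0.8, 0, clip = TRUE), 1)
  expect_equal(decayed_learning_rate(0.8, 0, clip = FALSE), 1.3)
  # strictly decreasing in exposure, converging to the base rate
  rates <- decayed_learning_rate(0.3, 0:50)
  expect_true(all(diff(rates) < 0))
  expect_equal(decayed_learning_rate(0.3, 1e9), 0.3, tolerance = 1e-8)
  expect_error(decayed_learning_rate(1.2, 0), "alpha")
  expect_error(decayed_learning_rate(0.3, -1), "t_s")
})

test_that("surprise utility subtracts d times the absolute prediction error", {
  expect_equal(surprise_utility(40, 20, 0.5), 30)
  expect_equal(surprise_utility(7, 7, 0.9), 7)
  expect_equal(surprise_utility(0, 20, 1), -20)
  # perfectly predicted or d = 0 leaves the outcome untouched
  expect_equal(surprise_utility(13, 5, 0), 13)
  r <- runif(50, -10, 10); q <- runif(50, -10, 10)
  expect_true(all(surprise_utility(r, q, 0.7) <= r))
  expect_error(surprise_utility(Inf, 0, 0.5), "finite")
  expect_error(surprise_utility(1, 0, 1.5), "d")
})

test_that("utility transform hits the three anchors and is linear at a = 2", {
  expect_equal(utility_transform(0, a = 5), 0)
  expect_equal(utility_transform(20, a = 5), 20)
  expect_equal(utility_transform(40, a = 5), 100)
  expect_equal(utility_transform(c(0, 20, 40), a = 2), c(0, 20, 40))
  expect_error(utility_transform(30, a = 5), "continuous")
  # continuous extension: monotone, matches anchors, odd
  x <- seq(0, 60, by = 5)
  u <- utility_transform(x, a = 4, continuous = TRUE)
  expect_true(all(diff(u) > 0))
  expect_equal(utility_transform(-20, a = 4, continuous = TRUE),
               -utility_transform(20, a = 4, continuous = TRUE))
  expect_error(utility_transform(20, a = 0.5), "a must")
})

test_that("model_params validates parameter sets per model", {
  p <- model_params("surprise", alpha = 0.3, beta = 2, d = 0.5)
  expect_s3_class(p, "rl_params")
  expect_error(model_params("qlearning", alpha = 0.3, beta = 2, d = 0.5),
               "not used")
  expect_error(model_params("qlearning", alpha = 0.3), "missing")
  expect_error(model_params("surprise", alpha = 0.3, beta = 11, d = 0),
               "outside")
  v <- c(alpha = 0.3, beta = 2, d = 0.5)
  expect_equal(params_from_vector("surprise", v), p)
})

test_that("update_state moves only the chosen stimulus by the model's rule", {
  st <- agent_state(c("A", "B"))
  ql <- model_params("qlearning", alpha = 0.5, beta = 1)
  # constant rate: half-step toward the outcome
  st1 <- update_state(st, ql, "A", 1, decay = FALSE)
  expect_equal(unname(st1$Q), c(0.5, 0))
  expect_equal(unname(st1$T), c(1L, 0L))
  # decayed rate at first exposure: alpha' = 0.5 + 0.5 = 1, jump to r
  st2 <- update_state(st, ql, "A", 1, decay = TRUE)
  expect_equal(st2$Q[["A"]], 1)
  # risk-sensitive with zero prediction error: value frozen, count moves
  rs <- model_params("risk_sensitive", alpha_pos = 0.9, alpha_neg = 0.1,
                     beta = 1)
  st3 <- update_state(st, rs, "B", 0, decay = FALSE)
  expect_equal(st3$Q[["B"]], 0)
  expect_equal(st3$T[["B"]], 1L)
  # asymmetric rates engage by the sign of the prediction error
  st4 <- update_state(st, rs, "A", 1, decay = FALSE)
  expect_equal(st4$Q[["A"]], 0.9)
  st5 <- update_state(st4, rs, "A", -1, decay = FALSE)
  expect_equal(st5$Q[["A"]], 0.9 + 0.1 * (-1 - 0.9))
  expect_error(update_state(st, ql, "C", 1), "unknown stimulus")
})

test_that("choice probabilities are a stable softmax over the offered set", {
  st <- agent_state(c("A", "B", "C"))
  st$Q[] <- c(1, 0, -2)
  p <- model_params("qlearning", alpha = 0.1, beta = 2)
  pr <- choice_probabilities(st, p, c("A", "B"))
  expect_equal(unname(pr), c(1 / (1 + exp(-2)), 1 - 1 / (1 + exp(-2))))
  expect_equal(round(unname(pr), 4), c(0.8808, 0.1192))
  expect_equal(sum(pr), 1, tolerance = 1e-12)
  # beta = 0: uniform regardless of values
  p0 <- model_params("qlearning", alpha = 0.1, beta = 0)
  expect_equal(unname(choice_probabilities(st, p0, c("A", "C"))),
               c(0.5, 0.5))
  # equal values: 1/K by symmetry
  st$Q[] <- 3
  expect_equal(unname(choice_probabilities(st, p, c("A", "B", "C"))),
               rep(1 / 3, 3))
  # invariance to adding a constant, even a huge one (max-subtraction)
  st$Q[] <- c(1, 0, -2)
  pr1 <- choice_probabilities(st, p, c("A", "B", "C"))
  st$Q[] <- st$Q + 5000
  pr2 <- choice_probabilities(st, p, c("A", "B", "C"))
  expect_equal(pr1, pr2)
  expect_error(choice_probabilities(st, p, character(0)), "non-empty")
})

test_that("probabilities over random states are positive and sum to one", {
  withr::with_seed(5, {
    for (i in 1:25) {
      st <- agent_state(letters[1:4])
      st$Q[] <- rnorm(4, 0, 5)
      pm <- random_params(sample(c("qlearning", "surprise",
                                   "risk_sensitive", "utility"), 1))
      pr <- choice_probabilities(st, pm, letters[1:4])
      expect_equal(sum(pr), 1, tolerance = 1e-12)
      expect_true(all(pr > 0 & pr < 1))
    }
  })
})

test_that("nested models reproduce Q-learning trajectories exactly", {
  withr::with_seed(42, {
    for (i in 1:10) {
      task <- if (i %% 2 == 0) build_risk_task(i) else small_bandit(60)
      alpha <- runif(1)
      beta <- runif(1, 0, 1)
      ql <- model_params("qlearning", alpha = alpha, beta = beta)
      sess <- simulate_agent(ql, task, seed = 100 + i)
      base <- replay_session(ql, sess)
      su0 <- model_params("surprise", alpha = alpha, beta = beta, d = 0)
      expect_identical(replay_session(su0, sess), base)
      rs <- model_params("risk_sensitive", alpha_pos = alpha,
                         alpha_neg = alpha, beta = beta)
      expect_identical(replay_session(rs, sess), base)
      if (i %% 2 == 0) {
        # risky-task payoffs are {0, 20, 40}: a = 2 utility is identity
        ut <- model_params("utility", alpha = alpha, beta = beta, a = 2)
        expect_equal(replay_session(ut, sess), base)
      }
    }
  })
})

test_that("unchosen stimuli never change during a session replay", {
  withr::with_seed(7, {
    task <- small_bandit(30)
    pm <- model_params("surprise", alpha = 0.4, beta = 1, d = 0.6)
    sess <- simulate_agent(pm, task, seed = 1)
    tr <- replay_session(pm, sess)
    for (t in seq_len(nrow(sess))) {
      unchosen <- setdiff(colnames(tr), sess$choice[t])
      expect_identical(tr[t + 1L, unchosen], tr[t, unchosen])
    }
  })
})
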