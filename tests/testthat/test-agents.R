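test_that("the factorial family enumerates to 48 distinct specs", {
  fam <- enumerate_family()
  expect_length(fam, 48)
  labels <- sapply(fam, spec_label)
  expect_equal(anyDuplicated(labels), 0L)
  expect_equal(sum(sapply(fam, `[[`, "target") == "beta_pessimistic"), 16)
  expect_false(any(sapply(fam, `[[`, "has_static_bias")))
})

test_that("future-value targets follow their defining formulas", {
  q <- c(a1 = 0.8, a2 = 0.2)
  expect_equal(future_value(q, "beta_pessimistic", beta = 0.25), 0.35,
               tolerance = 1e-12)
  expect_equal(future_value(q, "q_learning"), 0.8)
  expect_equal(future_value(q, "sarsa", next_action = "a2"), 0.2)
  expect_equal(future_value(NULL, "q_learning"), 0)   # terminal
  expect_error(future_value(q, "sarsa"), "next action")
  # beta = 1 collapses to Q-learning on any table
  withr::with_seed(1, for (i in 1:20) {
    qr <- rnorm(2)
    expect_identical(future_value(qr, "beta_pessimistic", beta = 1),
                     future_value(qr, "q_learning"))
  })
  # all targets coincide on a singleton action set
  q1 <- c(a1 = 0.37)
  expect_equal(future_value(q1, "sarsa", next_action = "a1"),
               future_value(q1, "q_learning"))
  expect_equal(future_value(q1, "beta_pessimistic", beta = 0.2),
               future_value(q1, "q_learning"))
})

test_that("effective reward adds the bonus on free outcomes only", {
  expect_equal(effective_reward(1, "free", 0.3), 1.3)
  expect_equal(effective_reward(0, "free", 0.3), 0.3)
  expect_equal(effective_reward(1, "forced", 0.3), 1.0)
  expect_equal(effective_reward(0, "forced", 0.3), 0.0)
})

test_that("prediction error and update arithmetic are exact", {
  expect_equal(prediction_error(0.5, 1.2), 0.7, tolerance = 1e-12)
  expect_equal(prediction_error(0.4, 0, future = 0.6), 0.2,
               tolerance = 1e-12)
  expect_equal(prediction_error(0.35, 0.2, future = 0.15), 0)  # fixed point
  expect_equal(apply_update(0, 1, 0.5), 0.5)
  expect_equal(apply_update(0.8, 5, 0), 0.8)       # alpha = 0 freezes
  expect_error(apply_update(0, 1, 1.5), "learning rate")
  # repeated updates converge to the reward (geometric series oracle)
  r <- 0.7; alpha <- 0.3; q <- 0
  for (k in 1:60) q <- apply_update(q, prediction_error(q, r), alpha)
  expect_equal(q, r * (1 - (1 - alpha)^60), tolerance = 1e-12)
  expect_lt(abs(q - r), 1e-8)
})

test_that("softmax policy matches closed forms and is a proper distribution", {
  expect_equal(action_probabilities(c(0.5, 0.5), tau = 1),
               c(0.5, 0.5), ignore_attr = TRUE)
  expect_equal(action_probabilities(c(1, 0), tau = 1)[1],
               exp(1) / (exp(1) + 1), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(
    action_probabilities(c(0, 0), tau = 1, kappa = 0.5,
                         repeat_ind = c(1, 0))[1],
    exp(0.5) / (exp(0.5) + 1), tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(action_probabilities(c(0, 1), tau = 0), "temperature")
  withr::with_seed(3, for (i in 1:25) {
    pr <- action_probabilities(rnorm(2), tau = runif(1, 0.2, 3),
                               kappa = rnorm(1), repeat_ind = c(1, 0),
                               bias = rnorm(1), bias_ind = c(1, 0))
    expect_equal(sum(pr), 1, tolerance = 1e-12)
    expect_true(all(pr > 0 & pr < 1))
  })
})

test_that("softmax is shift invariant and approaches argmax as tau -> 0", {
  withr::with_seed(4, for (i in 1:20) {
    q <- rnorm(2)
    expect_equal(action_probabilities(q, tau = 0.7),
                 action_probabilities(q + 3.1, tau = 0.7),
                 tolerance = 1e-12)
    pr <- action_probabilities(q, tau = 1e-4)
    expect_equal(unname(pr[which.max(q)]), 1, tolerance = 1e-6)
  })
})

test_that("trial stepping updates the credited entries as specified", {
  cfg <- build_config("exp1a", seed = 1)
  spec <- new_model_spec("q_learning", n_alpha = 2)
  p <- new_params(alpha1 = 0.3, alpha2 = 0.5, tau1 = 0.2)

  # training forced trial: single update of the forced terminal entry
  qt <- new_q_table(cfg, q_init = 0)
  tr <- list(phase = "train", stage1_option = "forced",
             stage2_action = "a1", reward = 1)
  st <- step_trial(qt, tr, block_slot = 1, spec, p)
  expect_equal(st$q$q2forced[1, "a1"], 0.5, ignore_attr = TRUE)
  expect_length(st$probs, 0)       # no likelihood term for the forced press
  expect_equal(st$q$q1[1, "forced"], 0, ignore_attr = TRUE)
  expect_equal(st$q$q2free, qt$q2free)   # untouched entries

  # test free trial with bonus: two-step hand computation
  spec_b <- new_model_spec("q_learning", has_bonus = TRUE, n_alpha = 2)
  pb <- new_params(alpha1 = 0.3, alpha2 = 0.5, tau1 = 0.2, rho = 0.4)
  qt <- new_q_table(cfg, q_init = 0)
  tr <- list(phase = "test", stage1_option = "free", stage2_action = "a1",
             reward = 1)
  st <- step_trial(qt, tr, block_slot = 2, spec_b, pb)
  expect_named(st$probs, c("stage1", "stage2"))
  expect_equal(unname(st$probs), c(0.5, 0.5))  # flat table, no kappa/bias
  # stage-1 backup of max pre-update stage-2 value (0), then stage-2 update
  expect_equal(st$q$q1[1, "free"], 0, ignore_attr = TRUE)
  expect_equal(st$q$q2free[2, "a1"], 0.5 * (1 + 0.4), ignore_attr = TRUE)
  # free stage-1 value strictly increases on the next rewarded free trial
  st2 <- step_trial(st$q, tr, block_slot = 2, spec_b, pb,
                    prev_stage1 = "free")
  expect_gt(st2$q$q1[1, "free"], st$q$q1[1, "free"])

  expect_error(step_trial(qt, list(phase = "train", stage1_option = "forced",
                                   stage2_action = "a2", reward = 0),
                          1, spec, p), "unknown")
})

test_that("q-table values stay inside the outcome hull", {
  cfg <- build_config("exp2", seed = 2)
  spec <- new_model_spec("q_learning", has_bonus = TRUE)
  p <- new_params(alpha1 = 0.9, alpha2 = 0.9, tau1 = 0.3, rho = 0.6)
  log <- simulate_subject(cfg, spec, p, seed = 5)
  # replay and track: all entries within [0, 1 + rho]
  qt <- new_q_table(cfg, q_init = 0)
  prev <- NULL
  slot <- 0; last_block <- -1
  for (i in seq_len(nrow(log))) {
    if (log$block_index[i] != last_block) {
      last_block <- log$block_index[i]; slot <- slot + 1; prev <- NULL
    }
    st <- step_trial(qt, as.list(log[i, ]), slot, spec, p, prev_stage1 = prev)
    qt <- st$q
    if (log$phase[i] == "test") prev <- log$stage1_option[i]
    vals <- c(qt$q1, qt$q2free, qt$q2forced)
    expect_true(all(vals >= 0 - 1e-12 & vals <= 1 + 0.6 + 1e-12))
  }
})
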