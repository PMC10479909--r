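test_that("simulated logs have the published trial counts and structure", {
  cfg <- build_config("exp1a", seed = 2)
  spec <- new_model_spec("q_learning")
  log <- simulate_subject(cfg, spec, new_params(), seed = 4)
  for (b in cfg$blocks) {
    lb <- log[log$block_index == b$block_index, ]
    train <- lb[lb$phase == "train", ]
    expect_equal(nrow(train), 2 * b$n_train_free)
    expect_equal(sum(train$stage1_option == "free"), b$n_train_free)
    expect_equal(nrow(lb[lb$phase == "test", ]), b$n_test)
  }
  expect_true(all(log$coherent))                       # exps 1-2
  expect_true(all(log$stage2_action == log$displayed_target))
  expect_true(all(log$stage1_is_choice == (log$phase == "test")))
  expect_true(all(log$stage2_action[log$stage1_option == "forced"] == "a1"))
  # deterministic replay
  expect_identical(log, simulate_subject(cfg, spec, new_params(), seed = 4))
  expect_false(identical(log,
                         simulate_subject(cfg, spec, new_params(), seed = 5)))
})

test_that("a non-learning agent expresses no preference despite a bonus", {
  cfg <- build_config("exp1a", seed = 1)
  spec <- new_model_spec("q_learning", has_bonus = TRUE)
  p <- new_params(alpha1 = 0, alpha2 = 0, tau1 = 0.3, rho = 0.8)
  cohort <- simulate_cohort(cfg, spec, p, n_subjects = 15, seed = 8)
  pref <- choice_preference(cohort$log)
  overall <- mean(pref$by_subject$pref)
  n <- sum(pref$by_subject$n_test)
  expect_lt(abs(overall - 0.5), 4 * sqrt(0.25 / n))
})

test_that("a bonus inflates free-choice preference in the parity block", {
  cfg <- build_config("exp1a", seed = 1)
  spec <- new_model_spec("q_learning", has_bonus = TRUE)
  p <- new_params(alpha1 = 0.3, alpha2 = 0.3, tau1 = 0.2, rho = 0.5)
  cohort <- simulate_cohort(cfg, spec, p, n_subjects = 40, seed = 10)
  pref <- choice_preference(cohort$log)
  parity <- pref$by_block$mean_pref[pref$by_block$block_index == 1]
  expect_gt(parity, 0.5)
})

test_that("empirical reward rates match the programmed probabilities", {
  cfg <- build_config("exp2", seed = 3)
  spec <- new_model_spec("q_learning")
  cohort <- simulate_cohort(cfg, spec,
                            new_params(alpha1 = 0.3, tau1 = 0.5),
                            n_subjects = 25, seed = 12)
  log <- cohort$log
  for (b in cfg$blocks) {
    forced <- log[log$block_index == b$block_index &
                  log$stage1_option == "forced", ]
    rate <- mean(forced$reward)
    expect_lt(abs(rate - b$p_forced),
              4 * sqrt(b$p_forced * (1 - b$p_forced) / nrow(forced)) + 1e-3)
  }
})

test_that("strategy agents reproduce their defining stay patterns exactly", {
  cfg <- build_config("exp3", seed = 1)
  patterns <- list(  # stay probability in cells rc, ru, ic, iu
    reward_based = c(rc = 1, ru = 0, ic = 1, iu = 0),
    swap_avoidance = c(rc = 1, ru = 1, ic = 0, iu = 0),
    model_based = c(rc = 1, ru = 0, ic = 0, iu = 1),
    control_maintenance = c(rc = 1, ru = 0, ic = 1, iu = 1))
  for (strat in names(patterns)) {
    log <- simulate_strategy_subject(cfg, strat, adherence = 1, seed = 21)
    st <- stay_probabilities(log)
    for (cell in names(patterns[[strat]])) {
      n <- st[[paste0("n_", cell)]]
      if (n > 0) {
        expect_equal(st[[paste0("stay_", cell)]],
                     unname(patterns[[strat]][cell]),
                     info = paste(strat, cell))
      }
    }
    # every cell observed at these incoherence levels
    expect_true(all(st[paste0("n_", c("rc", "ru"))] > 0))
  }
})

test_that("adherence 0.5 makes every stay cell uniform", {
  cfg <- build_config("exp3", seed = 1)
  logs <- do.call(rbind, lapply(1:20, function(i)
    simulate_strategy_subject(cfg, "model_based", adherence = 0.5,
                              subject_id = sprintf("s%02d", i), seed = i)))
  st <- stay_probabilities(logs)
  for (cell in c("rc", "ru", "ic", "iu")) {
    n <- sum(st[[paste0("n_", cell)]])
    pooled <- sum(st[[paste0("stay_", cell)]] * st[[paste0("n_", cell)]],
                  na.rm = TRUE) / n
    expect_lt(abs(pooled - 0.5), 4 * sqrt(0.25 / n))
  }
  expect_error(simulate_strategy_subject(cfg, "model_based",
                                         adherence = 0.3), "adherence")
  expect_error(simulate_strategy_subject(cfg, "oracle"), "arg")
})

test_that("cohorts are reproducible and prior draws respect supports", {
  cfg <- build_config("exp2", seed = 1)
  spec <- new_model_spec("beta_pessimistic", has_bonus = TRUE,
                         has_stickiness = TRUE)
  c1 <- simulate_cohort(cfg, spec, params = NULL, n_subjects = 8, seed = 33)
  c2 <- simulate_cohort(cfg, spec, params = NULL, n_subjects = 8, seed = 33)
  expect_identical(c1, c2)
  expect_equal(length(unique(c1$log$subject_id)), 8)
  expect_true(all(c1$params$alpha1 >= 0 & c1$params$alpha1 <= 1))
  expect_true(all(c1$params$beta >= 0 & c1$params$beta <= 1))
  expect_true(all(c1$params$tau1 > 0))
  # distinct trajectories across subjects
  rew <- tapply(c1$log$reward, c1$log$subject_id, paste, collapse = "")
  expect_gt(length(unique(rew)), 1)
})

test_that("pessimists lose their taste for choice as risk rises, optimists do not", {
  cfg <- build_config("exp1a", seed = 1)
  pess <- new_model_spec("beta_pessimistic")
  p_pess <- new_params(alpha1 = 0.3, alpha2 = 0.3, tau1 = 0.3, beta = 0.2)
  co_p <- simulate_cohort(cfg, pess, p_pess, n_subjects = 30, seed = 14)
  pref_p <- choice_preference(co_p$log)$by_block
  m_p <- pref_p$mean_pref[order(pref_p$block_index)]  # P = 0.5, 0.75, 1
  expect_true(all(diff(m_p) < 0))
  expect_lt(m_p[3], 0.3)   # preference reversed under maximal risk

  opti <- new_model_spec("q_learning", has_bonus = TRUE)
  p_opt <- new_params(alpha1 = 0.2, alpha2 = 0.2, tau1 = 0.3, rho = 0.5)
  co_o <- simulate_cohort(cfg, opti, p_opt, n_subjects = 30, seed = 14)
  pref_o <- choice_preference(co_o$log)$by_block
  m_o <- pref_o$mean_pref[order(pref_o$block_index)]
  expect_gt(m_o[3], 0.7)   # strong preference retained at P = 1
  expect_gt(m_o[3], m_o[1] - 0.1)
  expect_gt(m_o[3], m_p[3])
})
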