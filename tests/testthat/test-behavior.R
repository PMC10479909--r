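# minimal test-phase log builder: one subject, one block, given option /
# reward / action sequences
mini_test_log <- function(options, rewards = NULL, actions = NULL,
                          subject_id = "s1", block = 1L) {
  n <- length(options)
  if (is.null(rewards)) rewards <- rep(0L, n)
  if (is.null(actions)) actions <- rep("a1", n)
  data.frame(subject_id = subject_id, experiment = "exp2",
             block_index = block, phase = "test",
             trial_index = seq_len(n) - 1L, stage1_option = options,
             stage1_is_choice = TRUE, stage2_action = actions,
             displayed_target = actions, coherent = TRUE,
             reward = rewards, stringsAsFactors = FALSE)
}

test_that("choice preference counts free selections per block", {
  opts <- rep(c("free", "forced"), c(31, 17))  # 31 of 48 free
  pref <- choice_preference(mini_test_log(sample(opts)))
  expect_equal(pref$by_subject$pref, 31 / 48, tolerance = 1e-12)
  expect_equal(pref$by_subject$n_test, 48)
  all_free <- choice_preference(mini_test_log(rep("free", 10)))
  expect_equal(all_free$by_block$mean_pref, 1)
  expect_equal(nrow(pref$series), 48)
  expect_error(choice_preference(
    transform(mini_test_log(opts), phase = "train")), "no test trials")
})

test_that("preference series smoothing averages adjacent points", {
  expect_equal(smooth_series(c(0, 1, 0, 1)), c(0, 0.5, 0.5, 0.5))
  expect_equal(smooth_series(c(0.3)), 0.3)
})

test_that("conditional preference isolates alternators and perseverators", {
  alt <- mini_test_log(rep(c("free", "forced"), 10))
  ca <- conditional_stage1_preference(alt)
  expect_equal(ca$p_free_given_free, 0)
  expect_equal(ca$p_free_given_forced, 1)
  per <- mini_test_log(rep("free", 12))
  cp <- conditional_stage1_preference(per)
  expect_equal(cp$p_free_given_free, 1)
  expect_true(is.na(cp$p_free_given_forced))
  expect_equal(cp$n_given_forced, 0)
})

test_that("stay probabilities classify by the emitted action, not the display", {
  # two free trials: first incoherent (emitted a1, displayed a2, rewarded),
  # second emits a1 again => a stay in the rewarded & incoherent cell
  log <- data.frame(
    subject_id = "s1", experiment = "exp3", block_index = 1L,
    phase = "test", trial_index = 0:2,
    stage1_option = c("free", "forced", "free"),
    stage1_is_choice = TRUE,
    stage2_action = c("a1", "a1", "a1"),
    displayed_target = c("a2", "a1", "a1"),
    coherent = c(FALSE, TRUE, TRUE), reward = c(1L, 0L, 0L),
    stringsAsFactors = FALSE)
  st <- stay_probabilities(log)
  expect_equal(st$stay_ic, 1)   # stayed on the emitted action
  expect_equal(st$n_ic, 1)
  expect_equal(st$n_rc + st$n_ru + st$n_iu, 0)
  # intervening forced trial did not break the free-trial pairing
  expect_equal(sum(st[, grepl("^n_", names(st))]), 1)
})

test_that("the reversal point interpolates the indifference probability", {
  prefs <- data.frame(p_forced = c(0.75, 0.85, 0.95),
                      pref = c(0.9, 0.5, 0.1))
  expect_equal(reversal_point(prefs), 0.85, tolerance = 1e-6)
  above <- data.frame(p_forced = c(0.75, 0.85, 0.95),
                      pref = c(0.9, 0.8, 0.7))
  out <- reversal_point(above)
  expect_true(is.na(out))
  expect_match(attr(out, "reason"), "no crossing")
  flat <- data.frame(p_forced = c(0.75, 0.95), pref = c(0.6, 0.6))
  expect_true(is.na(reversal_point(flat)))
  expect_error(reversal_point(data.frame(p_forced = 0.75, pref = 0.5)),
               "two distinct")
})

test_that("reward-repetition odds ratio matches an inline contingency count", {
  withr::with_seed(11, {
    opts <- sample(c("free", "forced"), 400, replace = TRUE)
    rew <- sample(0:1, 400, replace = TRUE)
  })
  log <- mini_test_log(opts, rewards = rew)
  got <- reward_repetition_effect(log)
  prev_r <- rew[-400] == 1
  rep1 <- opts[-1] == opts[-400]
  tab <- table(factor(prev_r, c(TRUE, FALSE)), factor(rep1, c(TRUE, FALSE)))
  expect_equal(unname(got$table), unname(unclass(tab)), ignore_attr = TRUE)
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  expect_equal(got$odds_ratio, unname(or), tolerance = 1e-12)
  # reward-independent option choice gives an odds ratio near 1
  expect_lt(abs(log(got$odds_ratio)), 0.5)
})

test_that("zero cells trigger the Haldane-Anscombe correction", {
  # rewarded -> always repeat, unrewarded -> always switch
  opts <- c("free", "free", "forced", "forced", "free")
  rew <- c(1L, 0L, 1L, 0L, 1L)
  got <- reward_repetition_effect(mini_test_log(opts, rewards = rew))
  expect_true(is.finite(got$odds_ratio))
  expect_gt(got$odds_ratio, 1)
})

test_that("learning agents repeat rewarded first-stage selections", {
  # conditioning on the previous trial expresses reward tracking most
  # clearly when the options differ in value, as in the relative-value task
  cfg <- build_config("exp2", seed = 1)
  spec <- new_model_spec("q_learning")
  cohort <- simulate_cohort(cfg, spec,
                            new_params(alpha1 = 0.5, alpha2 = 0.5,
                                       tau1 = 0.2),
                            n_subjects = 20, seed = 19)
  or <- reward_repetition_effect(cohort$log)$odds_ratio
  expect_gt(or, 1)
})

test_that("trial logs survive a CSV round trip and reject corrupt rows", {
  cfg <- build_config("exp3", seed = 2)
  log <- simulate_strategy_subject(cfg, "reward_based", adherence = 0.8,
                                   seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trial_log(log, path)
  back <- read_trial_log(path)
  expect_equal(back, log, ignore_attr = TRUE)

  bad <- log
  bad$coherent[5] <- !bad$coherent[5]
  write_trial_log(bad, path)
  expect_error(read_trial_log(path), "row 5")

  bad2 <- log
  bad2$stage1_option[3] <- "maybe"
  write_trial_log(bad2, path)
  expect_error(read_trial_log(path), "row 3")

  writeLines(paste(choicerl:::TRIAL_LOG_COLUMNS, collapse = ","), path)
  expect_equal(nrow(read_trial_log(path)), 0)
})
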