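#!/usr/bin/env Rscript
# Descriptive behavioral summaries of the simulated cohorts: free-choice
# preference by block, the preference reversal point on the relative-value
# task, reward-repetition odds, conditional stage-1 preference and stay
# probabilities on the incoherence task. Run after 01_simulate_cohorts.R.

library(choicerl)

stopifnot(file.exists("results/exp1_optimists_log.csv"))

## exp 1: preference across reward probabilities --------------------------
for (cohort in c("optimists", "pessimists")) {
  log <- read_trial_log(sprintf("results/exp1_%s_log.csv", cohort))
  pref <- choice_preference(log)
  write.csv(pref$by_subject,
            sprintf("results/exp1_%s_pref_by_subject.csv", cohort),
            row.names = FALSE)
  message(cohort, " mean free-choice preference by block (P = 0.5, 0.75, 1): ",
          paste(round(pref$by_block$mean_pref[
            order(pref$by_block$block_index)], 3), collapse = ", "))
}

## exp 2: reversal point against p_forced ---------------------------------
log2 <- read_trial_log("results/exp2_cohort_log.csv")
pref2 <- choice_preference(log2)$by_subject
cfg2 <- build_config("exp2", seed = 1)
pmap <- sapply(cfg2$blocks, function(b) b$p_forced)
names(pmap) <- sapply(cfg2$blocks, function(b) b$block_index)
pref2$p_forced <- pmap[as.character(pref2$block_index)]
rev_pt <- reversal_point(pref2)
message("estimated preference reversal at p_forced = ", round(rev_pt, 3))
or <- reward_repetition_effect(log2)
message("reward-repetition odds ratio: ", round(or$odds_ratio, 2))
write.csv(pref2, "results/exp2_pref_by_subject.csv", row.names = FALSE)
writeLines(c(sprintf("reversal_point,%0.4f", rev_pt),
             sprintf("reward_repetition_or,%0.4f", or$odds_ratio)),
           "results/exp2_summary.csv")

## exp 3: conditional preference and stay probabilities -------------------
strategies <- c("reward_based", "swap_avoidance", "model_based",
                "control_maintenance")
stay_all <- do.call(rbind, lapply(strategies, function(strat) {
  log <- read_trial_log(sprintf("results/exp3_%s_log.csv", strat))
  st <- stay_probabilities(log)
  st$strategy <- strat
  st
}))
write.csv(stay_all, "results/exp3_stay_probabilities.csv", row.names = FALSE)
pooled <- aggregate(cbind(stay_rc, stay_ru, stay_ic, stay_iu) ~ strategy,
                    stay_all, mean, na.rm = TRUE)
print(pooled, digits = 2)

cond <- conditional_stage1_preference(
  read_trial_log("results/exp3_control_maintenance_log.csv"))
write.csv(cond, "results/exp3_conditional_preference.csv", row.names = FALSE)
message("control-maintenance cohort: P(free|prev free) = ",
        round(mean(cond$p_free_given_free, na.rm = TRUE), 3),
        ", P(free|prev forced) = ",
        round(mean(cond$p_free_given_forced, na.rm = TRUE), 3))
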