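#' Synthetic subjects for the two-stage task
#'
#' Generates complete per-subject trial logs: for each block an interleaved
#' training phase (experimenter-scheduled free/forced cues, equal counts)
#' followed by a test phase where the agent chooses the first-stage option
#' itself. Value updates run through both phases and training values carry
#' into test. All randomness derives from the supplied seed.
#'
#' @name simulate
NULL

TRIAL_LOG_COLUMNS <- c("subject_id", "experiment", "block_index", "phase",
                       "trial_index", "stage1_option", "stage1_is_choice",
                       "stage2_action", "displayed_target", "coherent",
                       "reward")

empty_trial_log <- function() {
  data.frame(subject_id = character(), experiment = character(),
             block_index = integer(), phase = character(),
             trial_index = integer(), stage1_option = character(),
             stage1_is_choice = logical(), stage2_action = character(),
             displayed_target = character(), coherent = logical(),
             reward = integer(), stringsAsFactors = FALSE)
}

# interleaved training schedule with equal free/forced counts
training_schedule <- function(block) {
  sample(rep(c("free", "forced"), c(block$n_train_free,
                                    block$n_train_forced)))
}

#' Simulate one model-based subject
#'
#' @param config a `task_config`.
#' @param spec a `model_spec` (its `q_init` initializes the value table).
#' @param params an `rl_params`.
#' @param subject_id identifier written into the log.
#' @param seed integer seed; replay is deterministic given
#'   `(seed, spec, params, config)`.
#' @param share_stage1 share first-stage values across blocks.
#' @return data.frame of trial records in chronological order.
#' @export
simulate_subject <- function(config, spec, params, subject_id = "sim01",
                             seed = 1L, share_stage1 = TRUE) {
  params <- expand_params(spec, params)
  local_rng(seed, {
    qt <- new_q_table(config, q_init = spec$q_init,
                      share_stage1 = share_stage1)
    rows <- vector("list", length(config$blocks))
    for (slot in seq_along(config$blocks)) {
      block <- config$blocks[[slot]]
      out <- simulate_block(qt, block, slot, config, spec, params,
                            subject_id)
      qt <- out$q
      rows[[slot]] <- out$log
    }
    do.call(rbind, rows)
  })
}

simulate_block <- function(qt, block, slot, config, spec, params,
                           subject_id) {
  p <- params
  n_fa <- n_forced_actions(config)
  sched <- training_schedule(block)
  n_total <- length(sched) + block$n_test
  rows <- vector("list", n_total)
  prev_stage1 <- NULL
  k <- 0L
  for (phase in c("train", "test")) {
    n_phase <- if (phase == "train") length(sched) else block$n_test
    for (i in seq_len(n_phase)) {
      if (phase == "train") {
        opt <- sched[[i]]
      } else {
        slot1 <- if (qt$share_stage1) 1L else slot
        rep_ind <- if (is.null(prev_stage1)) c(0, 0)
                   else as.numeric(c("free", "forced") == prev_stage1)
        pr1 <- action_probabilities(qt$q1[slot1, ], tau = p$tau1,
                                    kappa = p$kappa, repeat_ind = rep_ind,
                                    bias = p$bias, bias_ind = c(1, 0))
        opt <- if (stats::runif(1) < pr1[["free"]]) "free" else "forced"
      }
      if (opt == "free") {
        pr2 <- action_probabilities(qt$q2free[slot, ], tau = p$tau2)
        act <- if (stats::runif(1) < pr2[["a1"]]) "a1" else "a2"
      } else {
        act <- if (n_fa == 1L) "a1" else c("a1", "a2")[sample.int(2, 1)]
      }
      outc <- draw_outcome(block, opt, act)
      trial <- list(phase = phase, stage1_option = opt, stage2_action = act,
                    reward = outc$reward)
      st <- step_trial(qt, trial, slot, spec, params,
                       prev_stage1 = prev_stage1)
      qt <- st$q
      if (phase == "test") prev_stage1 <- opt
      k <- k + 1L
      rows[[k]] <- data.frame(
        subject_id = subject_id, experiment = config$experiment,
        block_index = block$block_index, phase = phase,
        trial_index = i - 1L, stage1_option = opt,
        stage1_is_choice = phase == "test", stage2_action = act,
        displayed_target = outc$displayed_target, coherent = outc$coherent,
        reward = outc$reward, stringsAsFactors = FALSE)
    }
  }
  list(q = qt, log = do.call(rbind, rows))
}

STRATEGIES <- c("reward_based", "swap_avoidance", "model_based",
                "control_maintenance")

# stay probability of a strategy given the last free trial's outcome
strategy_stay_prob <- function(strategy, rewarded, coherent, adherence) {
  stay_rule <- switch(strategy,
    reward_based = rewarded,
    swap_avoidance = coherent,
    model_based = (rewarded && coherent) || (!rewarded && !coherent),
    control_maintenance = if (coherent) rewarded else TRUE)
  if (stay_rule) adherence else 1 - adherence
}

#' Simulate a heuristic strategy subject (incoherence task)
#'
#' Strategy agents choose the free option at stage 1 with a fixed
#' probability and, on free trials, repeat or switch their second-stage
#' action according to a stay/switch rule applied to the most recent free
#' trial's outcome, with probability `adherence` (uniform otherwise):
#' \describe{
#'   \item{reward_based}{stay iff the last free trial was rewarded
#'     (illusory maximization of reward intake).}
#'   \item{swap_avoidance}{stay iff the last free trial was coherent
#'     (illusory minimization of incoherent states).}
#'   \item{model_based}{integrate reward and swap feedback: stay iff
#'     rewarded-and-coherent or unrewarded-and-incoherent.}
#'   \item{control_maintenance}{outcome-sensitive only when coherent; on
#'     incoherent trials always repeat the previous selection.}
#' }
#'
#' @param config a `task_config` (the incoherence variant, exp3).
#' @param strategy one of the four strategies above.
#' @param adherence probability of following the rule, in \[0.5, 1\].
#' @param p_free fixed stage-1 free-choice probability.
#' @param subject_id,seed as in [simulate_subject()].
#' @return data.frame of trial records.
#' @export
simulate_strategy_subject <- function(config, strategy, adherence = 1,
                                      p_free = 0.69, subject_id = "strat01",
                                      seed = 1L) {
  strategy <- match.arg(strategy, STRATEGIES)
  if (adherence < 0.5 || adherence > 1) {
    stop("adherence must lie in [0.5, 1]", call. = FALSE)
  }
  n_fa <- n_forced_actions(config)
  local_rng(seed, {
    rows <- list()
    for (block in config$blocks) {
      last_free <- NULL  # list(action, rewarded, coherent)
      sched <- training_schedule(block)
      for (phase in c("train", "test")) {
        n_phase <- if (phase == "train") length(sched) else block$n_test
        for (i in seq_len(n_phase)) {
          opt <- if (phase == "train") sched[[i]]
                 else if (stats::runif(1) < p_free) "free" else "forced"
          if (opt == "free") {
            if (is.null(last_free)) {
              act <- c("a1", "a2")[sample.int(2, 1)]
            } else {
              p_stay <- strategy_stay_prob(strategy, last_free$rewarded,
                                           last_free$coherent, adherence)
              act <- if (stats::runif(1) < p_stay) last_free$action
                     else setdiff(c("a1", "a2"), last_free$action)
            }
          } else {
            act <- if (n_fa == 1L) "a1" else c("a1", "a2")[sample.int(2, 1)]
          }
          outc <- draw_outcome(block, opt, act)
          if (opt == "free") {
            last_free <- list(action = act, rewarded = outc$reward == 1,
                              coherent = outc$coherent)
          }
          rows[[length(rows) + 1L]] <- data.frame(
            subject_id = subject_id, experiment = config$experiment,
            block_index = block$block_index, phase = phase,
            trial_index = i - 1L, stage1_option = opt,
            stage1_is_choice = phase == "test", stage2_action = act,
            displayed_target = outc$displayed_target,
            coherent = outc$coherent, reward = outc$reward,
            stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, rows)
  })
}

#' Simulate a cohort of independent subjects
#'
#' Each subject gets a distinct sub-seed drawn from the master seed, so the
#' whole cohort replays bit-identically from `(config, spec, seed)`.
#' Parameters are either fixed (shared by all subjects) or drawn per
#' subject from the fitting priors (see [draw_params_from_priors()]).
#'
#' @param config a `task_config`; @param spec a `model_spec`.
#' @param params an `rl_params` shared by all subjects, or `NULL` to draw
#'   each subject's parameters from the priors.
#' @param n_subjects cohort size.
#' @param seed master seed.
#' @param priors prior set used when drawing parameters.
#' @param overrides named parameter values forced on every prior draw
#'   (see [draw_params_from_priors()]).
#' @param permute_blocks randomize the order of non-fixed blocks per
#'   subject (as across subjects in the published designs).
#' @return list with `log` (all subjects, row-bound) and `params`
#'   (data.frame of generating parameters, one row per subject).
#' @export
simulate_cohort <- function(config, spec, params = NULL, n_subjects = 10L,
                            seed = 1L, priors = default_priors(),
                            overrides = NULL, permute_blocks = TRUE) {
  stopifnot(n_subjects >= 1)
  sub_seeds <- local_rng(seed, sample.int(.Machine$integer.max,
                                          n_subjects + 1L))
  par_list <- if (is.null(params)) {
    draw_params_from_priors(spec, n_subjects, seed = sub_seeds[[n_subjects + 1L]],
                            priors = priors, overrides = overrides)
  } else {
    replicate(n_subjects, expand_params(spec, params), simplify = FALSE)
  }
  ids <- sprintf("sub%03d", seq_len(n_subjects))
  logs <- lapply(seq_len(n_subjects), function(i) {
    cfg_i <- if (permute_blocks) permute_config(config, sub_seeds[[i]])
             else config
    simulate_subject(cfg_i, spec, par_list[[i]], subject_id = ids[[i]],
                     seed = sub_seeds[[i]])
  })
  par_df <- do.call(rbind, lapply(par_list, function(p)
    as.data.frame(unclass(p))))
  par_df <- cbind(subject_id = ids, par_df, stringsAsFactors = FALSE)
  list(log = do.call(rbind, logs), params = par_df)
}
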