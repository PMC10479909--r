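#' Temporal-difference learning agents for the two-stage task
#'
#' Agents maintain a look-up table of state-action values Q(s, a), updated
#' after each stage of a trial with the prediction error
#' \deqn{\delta_t = r_{t+1} + Z(s_{t+1}, a_{t+1}) - Q(s_t, a_t)}
#' and \eqn{Q(s_t, a_t) \leftarrow Q(s_t, a_t) + \alpha \delta_t}. The
#' future-value target Z takes one of three forms: the value of the action
#' actually taken next (one-step SARSA), the best next action value
#' (Q-learning), or a pessimism-weighted mixture
#' \eqn{\beta \max_{a'} Q + (1-\beta) \min_{a'} Q} that interpolates between
#' total risk aversion (\eqn{\beta = 0}) and Q-learning (\eqn{\beta = 1}).
#' An intrinsic free-choice bonus \eqn{\rho} is added to every outcome
#' obtained through the free option, so the inflated reward propagates into
#' subsequent value updates. Choices follow a softmax policy with per-stage
#' temperatures, optionally augmented by a stickiness term \eqn{\kappa} on
#' repeating the previous first-stage choice, or a static utility bias b on
#' the free option that never enters value updates.
#'
#' @name agents
NULL

TARGETS <- c("sarsa", "q_learning", "beta_pessimistic")

#' Construct a model specification
#'
#' One member of the factorial model family: future-value target, presence
#' of the free-choice bonus, one or two learning rates / temperatures,
#' stickiness, an optional static first-stage bias (kept outside the
#' 48-model family), and the Q-value initialization hyperparameter.
#'
#' @param target `"sarsa"`, `"q_learning"` or `"beta_pessimistic"`.
#' @param has_bonus free-choice bonus rho fitted (`TRUE`) or fixed at 0.
#' @param n_alpha 1 or 2 learning rates (stage 1 / stage 2).
#' @param n_tau 1 or 2 softmax temperatures.
#' @param has_stickiness stickiness kappa fitted or fixed at 0.
#' @param has_static_bias static free-option bias b fitted or fixed at 0.
#' @param q_init initial table fill, 0 or 0.5.
#' @return a `model_spec` object.
#' @export
new_model_spec <- function(target = "q_learning", has_bonus = FALSE,
                           n_alpha = 1L, n_tau = 1L,
                           has_stickiness = FALSE, has_static_bias = FALSE,
                           q_init = 0) {
  target <- match.arg(target, TARGETS)
  stopifnot(n_alpha %in% 1:2, n_tau %in% 1:2, q_init %in% c(0, 0.5))
  structure(list(target = target, has_bonus = isTRUE(has_bonus),
                 n_alpha = as.integer(n_alpha), n_tau = as.integer(n_tau),
                 has_stickiness = isTRUE(has_stickiness),
                 has_static_bias = isTRUE(has_static_bias),
                 q_init = q_init),
            class = "model_spec")
}

#' Canonical label of a model specification
#'
#' @param spec a `model_spec`.
#' @param with_qinit append the `@qinit` suffix.
#' @return string such as `"pess+bonus+2alpha+1tau+sticky@qinit0"`.
#' @export
spec_label <- function(spec, with_qinit = TRUE) {
  short <- c(sarsa = "sarsa", q_learning = "q", beta_pessimistic = "pess")
  parts <- c(short[[spec$target]],
             if (spec$has_bonus) "bonus",
             paste0(spec$n_alpha, "alpha"), paste0(spec$n_tau, "tau"),
             if (spec$has_stickiness) "sticky",
             if (spec$has_static_bias) "statbias")
  lab <- paste(parts, collapse = "+")
  if (with_qinit) paste0(lab, "@qinit", format(spec$q_init)) else lab
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec>", spec_label(x), "\n")
  invisible(x)
}

#' Enumerate the factorial model family
#'
#' The full crossing of 3 future-value targets x bonus on/off x 1-2 learning
#' rates x 1-2 temperatures x stickiness on/off: 48 specifications. Static
#' bias variants are excluded; each spec is later fit at both q_init values.
#'
#' @param q_init table initialization attached to every spec.
#' @return list of 48 `model_spec` objects.
#' @export
enumerate_family <- function(q_init = 0) {
  grid <- expand.grid(target = TARGETS, has_bonus = c(FALSE, TRUE),
                      n_alpha = 1:2, n_tau = 1:2,
                      has_stickiness = c(FALSE, TRUE),
                      stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(i)
    new_model_spec(grid$target[i], grid$has_bonus[i], grid$n_alpha[i],
                   grid$n_tau[i], grid$has_stickiness[i], q_init = q_init))
}

#' Construct a full parameter vector
#'
#' Parameters are stored fully expanded; constructors for specific specs
#' tie shared parameters ([expand_params()]). Temperatures are stored as
#' tau; fitting works on the inverse-temperature scale.
#'
#' @param alpha1,alpha2 learning rates in \[0, 1\] (stage 1 / stage 2).
#' @param tau1,tau2 softmax temperatures > 0.
#' @param beta pessimism weight in \[0, 1\] (1 = Q-learning).
#' @param rho free-choice bonus (reward units).
#' @param kappa stickiness.
#' @param bias static free-option bias.
#' @return a named list of class `rl_params`.
#' @export
new_params <- function(alpha1 = 0.3, alpha2 = alpha1, tau1 = 0.2,
                       tau2 = tau1, beta = 1, rho = 0, kappa = 0, bias = 0) {
  if (alpha1 < 0 || alpha1 > 1 || alpha2 < 0 || alpha2 > 1) {
    stop("learning rates must lie in [0, 1]", call. = FALSE)
  }
  if (tau1 <= 0 || tau2 <= 0) stop("temperatures must be > 0", call. = FALSE)
  if (beta < 0 || beta > 1) stop("beta must lie in [0, 1]", call. = FALSE)
  structure(list(alpha1 = alpha1, alpha2 = alpha2, tau1 = tau1, tau2 = tau2,
                 beta = beta, rho = rho, kappa = kappa, bias = bias),
            class = "rl_params")
}

#' Tie parameters to a model specification
#'
#' Enforces the spec's sharing and fixed-off constraints: a single learning
#' rate or temperature is shared across stages, and parameters of absent
#' features take their neutral values (rho = 0, kappa = 0, b = 0, beta = 1
#' for non-pessimistic targets).
#'
#' @param spec a `model_spec`; @param params an `rl_params`.
#' @return an `rl_params` consistent with `spec`.
#' @export
expand_params <- function(spec, params) {
  p <- params
  if (spec$n_alpha == 1L) p$alpha2 <- p$alpha1
  if (spec$n_tau == 1L) p$tau2 <- p$tau1
  if (!spec$has_bonus) p$rho <- 0
  if (!spec$has_stickiness) p$kappa <- 0
  if (!spec$has_static_bias) p$bias <- 0
  if (spec$target != "beta_pessimistic") p$beta <- 1
  p
}

#' Names of the free parameters of a spec
#'
#' Temperatures appear on the inverse scale (`invtau1`, `invtau2`) because
#' priors and optimizer bounds are defined on 1/tau.
#'
#' @param spec a `model_spec`.
#' @return character vector.
#' @export
free_param_names <- function(spec) {
  c("alpha1",
    if (spec$n_alpha == 2L) "alpha2",
    "invtau1",
    if (spec$n_tau == 2L) "invtau2",
    if (spec$target == "beta_pessimistic") "beta",
    if (spec$has_bonus) "rho",
    if (spec$has_stickiness) "kappa",
    if (spec$has_static_bias) "bias")
}

# free vector (invtau scale) -> full rl_params
params_from_vector <- function(spec, theta) {
  stopifnot(identical(names(theta), free_param_names(spec)))
  g <- function(nm, default) if (nm %in% names(theta)) theta[[nm]] else default
  new_params(
    alpha1 = theta[["alpha1"]],
    alpha2 = g("alpha2", theta[["alpha1"]]),
    tau1 = 1 / theta[["invtau1"]],
    tau2 = 1 / g("invtau2", theta[["invtau1"]]),
    beta = g("beta", 1), rho = g("rho", 0),
    kappa = g("kappa", 0), bias = g("bias", 0))
}

# full rl_params -> free vector (invtau scale)
params_to_vector <- function(spec, params) {
  p <- expand_params(spec, params)
  full <- c(alpha1 = p$alpha1, alpha2 = p$alpha2,
            invtau1 = 1 / p$tau1, invtau2 = 1 / p$tau2,
            beta = p$beta, rho = p$rho, kappa = p$kappa, bias = p$bias)
  full[free_param_names(spec)]
}

#' Future-value target Z
#'
#' @param q_next values of the actions available at the next state; `NULL`
#'   for a terminal state (returns 0).
#' @param target `"sarsa"`, `"q_learning"` or `"beta_pessimistic"`.
#' @param next_action index or name of the next action (required for SARSA
#'   at non-terminal states).
#' @param beta pessimism weight.
#' @return scalar Z value.
#' @export
future_value <- function(q_next, target = "q_learning", next_action = NULL,
                         beta = 1) {
  target <- match.arg(target, TARGETS)
  if (is.null(q_next) || length(q_next) == 0) return(0)
  switch(target,
    sarsa = {
      if (is.null(next_action)) {
        stop("SARSA requires the next action at non-terminal states",
             call. = FALSE)
      }
      unname(q_next[[next_action]])
    },
    q_learning = max(q_next),
    beta_pessimistic = beta * max(q_next) + (1 - beta) * min(q_next))
}

#' Effective reward with the free-choice bonus
#'
#' The bonus rho is added to every outcome obtained through the free option,
#' rewarded or not: \eqn{r_{t+1} = r^{extrinsic}_{t+1} + \rho}.
#'
#' @param extrinsic extrinsic reward, 0 or 1.
#' @param option `"free"` or `"forced"`.
#' @param rho bonus.
#' @return effective reward.
#' @export
effective_reward <- function(extrinsic, option, rho = 0) {
  stopifnot(extrinsic %in% c(0, 1))
  if (option == "free") extrinsic + rho else extrinsic + 0
}

#' Prediction error
#'
#' \eqn{\delta = r_{eff} + Z - Q(s, a)}. At the first-to-second stage
#' transition the effective reward is 0 (rewards follow terminal actions
#' only); at the second-stage update the future value is 0.
#'
#' @param q_sa current value Q(s, a).
#' @param r_effective effective reward.
#' @param future future-value target Z (default 0, terminal).
#' @return scalar delta.
#' @export
prediction_error <- function(q_sa, r_effective, future = 0) {
  r_effective + future - q_sa
}

#' Apply a value update
#'
#' @param q_sa current value.
#' @param delta prediction error.
#' @param alpha learning rate in \[0, 1\].
#' @return updated value `q_sa + alpha * delta`.
#' @export
apply_update <- function(q_sa, delta, alpha) {
  if (alpha < 0 || alpha > 1) {
    stop("learning rate must lie in [0, 1]", call. = FALSE)
  }
  q_sa + alpha * delta
}

#' Softmax action probabilities with stickiness and static bias
#'
#' \eqn{\pi(a_k) \propto \exp(u_k / \tau)} with
#' \eqn{u_k = Q(s, a_k) + \kappa C(a_k) + b B(a_k)}, where C indicates
#' repetition of the previous first-stage choice and B marks the free
#' option under the static-bias variant.
#'
#' @param q values of the two available actions (named or not).
#' @param tau softmax temperature, > 0.
#' @param kappa stickiness weight; @param repeat_ind 0/1 indicator pair C.
#' @param bias static bias weight; @param bias_ind 0/1 indicator pair B.
#' @return probability pair summing to 1 (names preserved).
#' @export
action_probabilities <- function(q, tau, kappa = 0, repeat_ind = c(0, 0),
                                 bias = 0, bias_ind = c(0, 0)) {
  if (tau <= 0) stop("temperature must be > 0", call. = FALSE)
  stopifnot(length(q) == 2)
  u <- (q + kappa * repeat_ind + bias * bias_ind) / tau
  u <- u - max(u)
  e <- exp(u)
  e / sum(e)
}

#' Initialize the state-action value table
#'
#' Second-stage entries are per block (fresh fractals each block); the two
#' first-stage entries (free / forced cues) are shared across blocks by
#' default, since the same cue targets are reused within an experiment.
#'
#' @param config a `task_config`.
#' @param q_init initial fill, 0 or 0.5.
#' @param share_stage1 share the first-stage entries across blocks.
#' @return a `q_table`: list with matrices `q1` (rows = blocks or 1 shared
#'   row; columns free/forced), `q2free` (blocks x 2) and `q2forced`
#'   (blocks x 1 or 2).
#' @export
new_q_table <- function(config, q_init = 0, share_stage1 = TRUE) {
  stopifnot(q_init %in% c(0, 0.5))
  nb <- length(config$blocks)
  n1 <- if (share_stage1) 1L else nb
  structure(list(
    q1 = matrix(q_init, n1, 2, dimnames = list(NULL, c("free", "forced"))),
    q2free = matrix(q_init, nb, 2, dimnames = list(NULL, c("a1", "a2"))),
    q2forced = matrix(q_init, nb, n_forced_actions(config),
                      dimnames = list(NULL,
                                      c("a1", "a2")[seq_len(n_forced_actions(config))])),
    share_stage1 = share_stage1), class = "q_table")
}

#' Replay one trial through an agent
#'
#' Emits the policy probability of each free decision in the trial (the
#' first-stage choice in the test phase; the second-stage choice on
#' free-option trials in both phases), then applies the stage-1 backup
#' using pre-update stage-2 values, followed by the stage-2 update with the
#' effective reward. Forced decisions contribute probability 1 but still
#' drive updates. On incoherent trials the stage-2 update credits the
#' emitted action with the reward as delivered.
#'
#' @param qt a `q_table`.
#' @param trial one trial record (list or one-row data.frame) with fields
#'   `phase`, `stage1_option`, `stage2_action`, `reward`.
#' @param block_slot index of the trial's block in the `q_table`.
#' @param spec a `model_spec`; @param params an `rl_params`.
#' @param prev_stage1 the previous test trial's first-stage choice within
#'   the block, or `NULL` at the first test trial (stickiness inactive).
#' @return list with the updated `q` table and `probs`, a named vector of
#'   the emitted decision probabilities (`stage1` and/or `stage2`).
#' @export
step_trial <- function(qt, trial, block_slot, spec, params,
                       prev_stage1 = NULL) {
  p <- expand_params(spec, params)
  opt <- as.character(trial$stage1_option)
  emitted <- as.character(trial$stage2_action)
  slot1 <- if (qt$share_stage1) 1L else block_slot
  q2 <- if (opt == "free") qt$q2free[block_slot, ]
        else qt$q2forced[block_slot, , drop = TRUE]
  if (!emitted %in% names(qt$q2free[block_slot, ]) ||
      (opt == "forced" && !emitted %in% colnames(qt$q2forced))) {
    stop("trial references an action unknown to the task graph",
         call. = FALSE)
  }
  probs <- c()
  if (identical(as.character(trial$phase), "test")) {
    rep_ind <- if (is.null(prev_stage1)) c(0, 0)
               else as.numeric(c("free", "forced") == prev_stage1)
    pr1 <- action_probabilities(qt$q1[slot1, ], tau = p$tau1,
                                kappa = p$kappa, repeat_ind = rep_ind,
                                bias = p$bias, bias_ind = c(1, 0))
    probs <- c(probs, stage1 = unname(pr1[[opt]]))
  }
  if (opt == "free") {
    pr2 <- action_probabilities(qt$q2free[block_slot, ], tau = p$tau2)
    probs <- c(probs, stage2 = unname(pr2[[emitted]]))
  }
  # stage-1 backup from pre-update stage-2 values
  z <- future_value(q2, spec$target, next_action = emitted, beta = p$beta)
  d1 <- prediction_error(qt$q1[slot1, opt], r_effective = 0, future = z)
  qt$q1[slot1, opt] <- apply_update(qt$q1[slot1, opt], d1, p$alpha1)
  # stage-2 update with effective reward; terminal, so Z = 0
  reff <- effective_reward(trial$reward, opt, p$rho)
  if (opt == "free") {
    d2 <- prediction_error(qt$q2free[block_slot, emitted], reff)
    qt$q2free[block_slot, emitted] <-
      apply_update(qt$q2free[block_slot, emitted], d2, p$alpha2)
  } else {
    d2 <- prediction_error(qt$q2forced[block_slot, emitted], reff)
    qt$q2forced[block_slot, emitted] <-
      apply_update(qt$q2forced[block_slot, emitted], d2, p$alpha2)
  }
  list(q = qt, probs = probs)
}
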