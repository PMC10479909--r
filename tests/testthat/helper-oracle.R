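# Independent straight-line replay of the agent equations, written directly
# from the update rules with its own bookkeeping. Used as the oracle against
# the package's likelihood path; deliberately shares no code with it.
oracle_loglik <- function(log, spec, params, config, share_stage1 = TRUE) {
  a1 <- params$alpha1
  a2 <- if (spec$n_alpha == 2) params$alpha2 else params$alpha1
  t1 <- params$tau1
  t2 <- if (spec$n_tau == 2) params$tau2 else params$tau1
  be <- if (spec$target == "beta_pessimistic") params$beta else 1
  rho <- if (spec$has_bonus) params$rho else 0
  ka <- if (spec$has_stickiness) params$kappa else 0
  bb <- if (spec$has_static_bias) params$bias else 0
  nfa <- if (config$experiment == "exp3") 2L else 1L
  blocks <- unique(log$block_index)
  nb <- length(blocks)

  # value tables as plain vectors
  Q1 <- matrix(spec$q_init, if (share_stage1) 1 else nb, 2)  # free, forced
  Q2F <- matrix(spec$q_init, nb, 2)
  Q2C <- matrix(spec$q_init, nb, nfa)

  terms <- numeric(0)
  prev <- NA_character_
  cur_blk <- NA
  for (r in seq_len(nrow(log))) {
    blk <- match(log$block_index[r], blocks)
    if (!identical(blk, cur_blk)) { cur_blk <- blk; prev <- NA_character_ }
    s1 <- if (share_stage1) 1 else blk
    opt <- log$stage1_option[r]
    act <- if (log$stage2_action[r] == "a1") 1L else 2L
    if (log$phase[r] == "test") {
      uf <- Q1[s1, 1] + bb + if (identical(prev, "free")) ka else 0
      uo <- Q1[s1, 2] + if (identical(prev, "forced")) ka else 0
      pfree <- 1 / (1 + exp((uo - uf) / t1))
      terms <- c(terms, log(if (opt == "free") pfree else 1 - pfree))
    }
    if (opt == "free") {
      pa1 <- 1 / (1 + exp((Q2F[blk, 2] - Q2F[blk, 1]) / t2))
      terms <- c(terms, log(if (act == 1L) pa1 else 1 - pa1))
      z <- switch(spec$target,
                  sarsa = Q2F[blk, act],
                  q_learning = max(Q2F[blk, ]),
                  beta_pessimistic = be * max(Q2F[blk, ]) +
                    (1 - be) * min(Q2F[blk, ]))
    } else {
      qs <- Q2C[blk, seq_len(nfa)]
      z <- switch(spec$target,
                  sarsa = Q2C[blk, act],
                  q_learning = max(qs),
                  beta_pessimistic = be * max(qs) + (1 - be) * min(qs))
    }
    col <- if (opt == "free") 1 else 2
    Q1[s1, col] <- Q1[s1, col] + a1 * (z - Q1[s1, col])
    if (log$phase[r] == "test") prev <- opt
    reff <- log$reward[r] + if (opt == "free") rho else 0
    if (opt == "free") {
      Q2F[blk, act] <- Q2F[blk, act] + a2 * (reff - Q2F[blk, act])
    } else {
      Q2C[blk, act] <- Q2C[blk, act] + a2 * (reff - Q2C[blk, act])
    }
  }
  list(loglik = sum(terms), n_obs = length(terms), terms = terms)
}

# random short single-subject log consistent with `config` (uses only the
# first block); train rows precede test rows
random_mini_log <- function(config, n_train = 3L, n_test = 2L, seed = 1L,
                            subject_id = "mini") {
  blk <- config$blocks[[1]]
  nfa <- if (config$experiment == "exp3") 2L else 1L
  withr::with_seed(seed, {
    n <- n_train + n_test
    opt <- c(sample(c("free", "forced"), n_train, replace = TRUE),
             sample(c("free", "forced"), n_test, replace = TRUE))
    act <- ifelse(opt == "free", sample(c("a1", "a2"), n, replace = TRUE),
                  if (nfa == 1L) "a1"
                  else sample(c("a1", "a2"), n, replace = TRUE))
    swap <- stats::runif(n) < blk$incoherence
    disp <- ifelse(swap, ifelse(act == "a1", "a2", "a1"), act)
    data.frame(
      subject_id = subject_id, experiment = config$experiment,
      block_index = blk$block_index,
      phase = rep(c("train", "test"), c(n_train, n_test)),
      trial_index = c(seq_len(n_train), seq_len(n_test)) - 1L,
      stage1_option = opt,
      stage1_is_choice = rep(c(FALSE, TRUE), c(n_train, n_test)),
      stage2_action = act, displayed_target = disp, coherent = !swap,
      reward = sample(0:1, n, replace = TRUE),
      stringsAsFactors = FALSE)
  })
}

# random parameter set drawn loosely over the supported ranges
random_params <- function(seed = 1L) {
  withr::with_seed(seed, new_params(
    alpha1 = stats::runif(1, 0.05, 0.95),
    alpha2 = stats::runif(1, 0.05, 0.95),
    tau1 = stats::runif(1, 0.1, 2), tau2 = stats::runif(1, 0.1, 2),
    beta = stats::runif(1), rho = stats::rnorm(1),
    kappa = stats::rnorm(1), bias = stats::rnorm(1)))
}
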