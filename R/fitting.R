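#' MAP fitting of the model family
#'
#' The likelihood replays a subject's full log (training + test, every
#' block, in chronological order) through the agent's update equations and
#' sums the log softmax probabilities of the modeled decisions:
#' second-stage choices on free-option trials in both phases and
#' first-stage choices in the test phase. Forced key presses are excluded
#' (probability 1) but still drive value updates, and training values carry
#' into the test phase. Estimation maximizes likelihood times prior with a
#' bounded quasi-Newton optimizer from several prior-drawn starts.
#'
#' @name fitting
NULL

# encode a single-subject log into the integer arrays the compiled
# likelihood consumes; trials must be in chronological order
prepare_trial_data <- function(log, config) {
  missing <- setdiff(TRIAL_LOG_COLUMNS, names(log))
  if (length(missing) > 0) {
    stop("trial log lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (length(unique(log$subject_id)) != 1) {
    stop("likelihood expects a single subject's log", call. = FALSE)
  }
  slots <- match(log$block_index, unique(log$block_index))
  n_blocks <- max(slots)
  if (n_blocks > length(config$blocks)) {
    stop("log has ", n_blocks, " blocks but the config has only ",
         length(config$blocks), call. = FALSE)
  }
  list(block_slot = as.integer(slots),
       is_test = as.integer(log$phase == "test"),
       is_free = as.integer(log$stage1_option == "free"),
       action = as.integer(ifelse(log$stage2_action == "a1", 1L, 2L)),
       reward = as.numeric(log$reward),
       n_blocks = as.integer(n_blocks),
       n_forced_actions = n_forced_actions(config))
}

par_array <- function(spec, params) {
  p <- expand_params(spec, params)
  c(p$alpha1, p$alpha2, p$tau1, p$tau2, p$beta, p$rho, p$kappa, p$bias)
}

target_code <- function(target) {
  match(target, TARGETS) - 1L
}

#' Trial-level log-likelihood of one subject's log
#'
#' @param log single-subject trial log (chronological).
#' @param spec a `model_spec`; its `q_init` initializes the value table.
#' @param params an `rl_params`.
#' @param config the `task_config` the log was generated under.
#' @param share_stage1 share first-stage values across blocks.
#' @return list with `loglik` and `n_obs` (count of modeled decisions).
#' @export
log_likelihood <- function(log, spec, params, config, share_stage1 = TRUE) {
  td <- prepare_trial_data(log, config)
  out <- loglik_cpp(td$block_slot, td$is_test, td$is_free, td$action,
                    td$reward, td$n_blocks, td$n_forced_actions,
                    share_stage1, target_code(spec$target), spec$q_init,
                    par_array(spec, params))
  list(loglik = out$loglik, n_obs = out$n_obs)
}

#' Log posterior (likelihood plus priors over the free parameters)
#'
#' Priors on temperatures are applied on the inverse-temperature scale.
#' Returns `-Inf` outside the prior support.
#'
#' @inheritParams log_likelihood
#' @param priors a `prior_set`.
#' @return scalar log posterior.
#' @export
log_posterior <- function(log, spec, params, config,
                          priors = default_priors(), share_stage1 = TRUE) {
  theta <- params_to_vector(spec, params)
  lp <- log_prior(spec, theta, priors)
  if (!is.finite(lp)) return(-Inf)
  ll <- log_likelihood(log, spec, params, config, share_stage1)$loglik
  ll + lp
}

map_bounds <- function(spec) {
  nms <- free_param_names(spec)
  eps <- 1e-6
  lower <- vapply(nms, function(nm) switch(nm,
    alpha1 = eps, alpha2 = eps, beta = eps,
    invtau1 = eps, invtau2 = eps, -Inf), numeric(1))
  upper <- vapply(nms, function(nm) switch(nm,
    alpha1 = 1 - eps, alpha2 = 1 - eps, beta = 1 - eps, Inf), numeric(1))
  list(lower = lower, upper = upper)
}

#' MAP estimation for one subject and one model specification
#'
#' Maximizes the log posterior with L-BFGS-B under box bounds
#' (alpha, beta in \[0, 1\]; 1/tau >= 0, optimized on the inverse scale;
#' rho, kappa, b unbounded), from `n_restarts` starts drawn from the
#' priors; returns the best converged restart. Deterministic given `seed`.
#'
#' @inheritParams log_posterior
#' @param n_restarts number of random initializations.
#' @param seed integer seed for the starts.
#' @return a `fit_result`: list with `spec`, `params_hat`, `theta_hat`,
#'   `log_likelihood`, `log_posterior`, `n_obs`, `n_params`, `bic`,
#'   `n_restarts_converged`.
#' @export
fit_map <- function(log, spec, config, priors = default_priors(),
                    n_restarts = 10L, seed = 1L, share_stage1 = TRUE) {
  stopifnot(n_restarts >= 1)
  td <- prepare_trial_data(log, config)
  n_obs_total <- sum(td$is_test) + sum(td$is_free)
  if (n_obs_total == 0) {
    stop("log contains no modeled decisions; nothing to fit", call. = FALSE)
  }
  nms <- free_param_names(spec)
  tcode <- target_code(spec$target)
  negpost <- function(theta) {
    names(theta) <- nms
    lp <- log_prior(spec, theta, priors)
    if (!is.finite(lp)) return(1e10)
    params <- params_from_vector(spec, theta)
    out <- loglik_cpp(td$block_slot, td$is_test, td$is_free, td$action,
                      td$reward, td$n_blocks, td$n_forced_actions,
                      share_stage1, tcode, spec$q_init,
                      par_array(spec, params))
    v <- -(out$loglik + lp)
    if (!is.finite(v)) 1e10 else v
  }
  bounds <- map_bounds(spec)
  starts <- local_rng(seed, lapply(seq_len(n_restarts), function(i) {
    th <- vapply(nms, function(nm) priors[[nm]]$sample(1), numeric(1))
    names(th) <- nms
    th
  }))
  best <- NULL
  n_conv <- 0L
  for (th0 in starts) {
    res <- tryCatch(
      stats::optim(th0, negpost, method = "L-BFGS-B",
                   lower = bounds$lower, upper = bounds$upper,
                   control = list(maxit = 500L)),
      error = function(e) NULL)
    if (is.null(res)) next
    conv <- res$convergence == 0
    if (conv) n_conv <- n_conv + 1L
    if (is.null(best) ||
        (conv && !best$conv) ||
        (conv == best$conv && res$value < best$value)) {
      best <- list(par = res$par, value = res$value, conv = conv)
    }
  }
  if (is.null(best)) {
    stop("all ", n_restarts, " restarts failed for spec ", spec_label(spec),
         call. = FALSE)
  }
  if (n_conv == 0L) {
    warning("no restart reported convergence for spec ", spec_label(spec),
            "; returning the best attempt", call. = FALSE)
  }
  theta <- best$par
  names(theta) <- nms
  params_hat <- params_from_vector(spec, theta)
  out <- loglik_cpp(td$block_slot, td$is_test, td$is_free, td$action,
                    td$reward, td$n_blocks, td$n_forced_actions,
                    share_stage1, tcode, spec$q_init,
                    par_array(spec, params_hat))
  k <- length(nms)
  structure(list(
    spec = spec, params_hat = params_hat, theta_hat = theta,
    log_likelihood = out$loglik,
    log_posterior = out$loglik + log_prior(spec, theta, priors),
    n_obs = out$n_obs, n_params = k,
    bic = k * log(out$n_obs) - 2 * out$loglik,
    n_restarts_converged = n_conv), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result>", spec_label(x$spec), "\n")
  cat(sprintf("  logLik %.2f  logPost %.2f  n_obs %d  k %d  BIC %.2f\n",
              x$log_likelihood, x$log_posterior, x$n_obs, x$n_params,
              x$bic))
  invisible(x)
}

#' Fit a set of model specifications to one subject
#'
#' Fits every spec at each Q-initialization and collects one row per fit,
#' ready for [select_model()].
#'
#' @inheritParams fit_map
#' @param specs list of `model_spec`s (default: the 48-member family).
#' @param q_inits Q-initialization hyperparameter values to cross with
#'   `specs`.
#' @return data.frame with columns `label` (spec including q_init),
#'   `q_init`, `bic`, `log_lik`, `log_post`, `n_obs`, `n_params` and the
#'   fitted parameters; the `fit_result` objects are attached as the
#'   `"fits"` attribute.
#' @export
fit_family <- function(log, config, specs = enumerate_family(),
                       q_inits = c(0, 0.5), priors = default_priors(),
                       n_restarts = 10L, seed = 1L, share_stage1 = TRUE) {
  fits <- list()
  for (spec in specs) {
    for (qi in q_inits) {
      s <- spec
      s$q_init <- qi
      fits[[spec_label(s)]] <-
        fit_map(log, s, config, priors, n_restarts, seed, share_stage1)
    }
  }
  rows <- lapply(fits, function(f) {
    p <- f$params_hat
    data.frame(label = spec_label(f$spec), q_init = f$spec$q_init,
               bic = f$bic, log_lik = f$log_likelihood,
               log_post = f$log_posterior, n_obs = f$n_obs,
               n_params = f$n_params,
               alpha1 = p$alpha1, alpha2 = p$alpha2, tau1 = p$tau1,
               tau2 = p$tau2, beta = p$beta, rho = p$rho, kappa = p$kappa,
               bias = p$bias, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  attr(out, "fits") <- fits
  out
}
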