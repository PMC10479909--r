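#' Priors for MAP estimation
#'
#' Independent priors over the free parameters, applied on the scale on
#' which each parameter is optimized: learning rates and the pessimism
#' weight on \[0, 1\], temperatures on the inverse-temperature scale
#' 1/tau >= 0, and the bonus / stickiness / static-bias terms on the real
#' line:
#' alpha ~ Beta(1.1, 1.1); 1/tau ~ Gamma(shape 1.2, scale 5);
#' beta ~ Beta(1.1, 1.1); rho, kappa, b ~ Normal(0, 1).
#'
#' @return a named list (class `prior_set`); each element carries `logd`
#'   (log density), `sample` (random draws) and `quantile` functions.
#' @export
default_priors <- function() {
  beta_prior <- list(
    logd = function(x) stats::dbeta(x, 1.1, 1.1, log = TRUE),
    sample = function(n) stats::rbeta(n, 1.1, 1.1),
    quantile = function(p) stats::qbeta(p, 1.1, 1.1))
  gamma_prior <- list(
    logd = function(x) stats::dgamma(x, shape = 1.2, scale = 5, log = TRUE),
    sample = function(n) stats::rgamma(n, shape = 1.2, scale = 5),
    quantile = function(p) stats::qgamma(p, shape = 1.2, scale = 5))
  normal_prior <- list(
    logd = function(x) stats::dnorm(x, 0, 1, log = TRUE),
    sample = function(n) stats::rnorm(n, 0, 1),
    quantile = function(p) stats::qnorm(p, 0, 1))
  structure(list(alpha1 = beta_prior, alpha2 = beta_prior,
                 invtau1 = gamma_prior, invtau2 = gamma_prior,
                 beta = beta_prior, rho = normal_prior,
                 kappa = normal_prior, bias = normal_prior),
            class = "prior_set")
}

# sum of log prior densities over the free parameters of `spec`
log_prior <- function(spec, theta, priors = default_priors()) {
  nms <- free_param_names(spec)
  sum(vapply(nms, function(nm) priors[[nm]]$logd(theta[[nm]]), numeric(1)))
}

#' Draw generating parameters from the priors
#'
#' Used to seed simulated cohorts and recovery runs. Inverse temperatures
#' are capped at the 99th prior percentile so that draws stay in the
#' identifiable regime (extreme 1/tau makes choices deterministic and the
#' remaining parameters unconstrained by the data).
#'
#' @param spec a `model_spec` (only its free parameters are drawn; the
#'   rest sit at their neutral values).
#' @param n number of parameter sets.
#' @param seed integer seed.
#' @param priors a `prior_set`.
#' @param overrides named list of parameter values forced on every draw
#'   (e.g. `list(beta = 0.3)`).
#' @return list of `rl_params`.
#' @export
draw_params_from_priors <- function(spec, n, seed = 1L,
                                    priors = default_priors(),
                                    overrides = NULL) {
  nms <- free_param_names(spec)
  cap <- priors$invtau1$quantile(0.99)
  local_rng(seed, {
    lapply(seq_len(n), function(i) {
      theta <- vapply(nms, function(nm) priors[[nm]]$sample(1), numeric(1))
      names(theta) <- nms
      for (nm in intersect(nms, c("invtau1", "invtau2"))) {
        theta[[nm]] <- min(theta[[nm]], cap)
      }
      p <- params_from_vector(spec, theta)
      for (nm in names(overrides)) p[[nm]] <- overrides[[nm]]
      expand_params(spec, p)
    })
  })
}
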