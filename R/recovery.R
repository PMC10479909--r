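#' Parameter and model recovery on simulated cohorts
#'
#' Validation pipelines: simulate subjects from known specifications and
#' parameters, refit, and tabulate how well the generating parameters are
#' estimated (parameter recovery) and how often the generating model
#' family is re-selected (model recovery).
#'
#' @name recovery
NULL

#' Parameter recovery for one specification
#'
#' Draws true parameters from the priors (inverse temperatures capped at
#' the 99th prior percentile for identifiability), simulates each subject
#' under `config`, refits with the generating spec, and tabulates true
#' against estimated values. Failed fits are recorded and skipped.
#'
#' @param spec generating (and fitting) `model_spec`.
#' @param config a `task_config` (the graded-probability variant has the
#'   largest trial counts and best identifiability).
#' @param n_subjects number of simulated subjects (>= 2).
#' @param seed master seed; the run is reproducible bit-for-bit.
#' @param n_restarts restarts per fit.
#' @param priors a `prior_set`.
#' @param overrides named parameter values forced on every generating draw.
#' @return a `recovery_report`: list with `report` (long data.frame of
#'   subject x parameter true/estimated pairs), `summary` (Spearman
#'   correlation and median absolute error per parameter), `n_subjects`,
#'   `n_failed`, `seed`.
#' @export
run_parameter_recovery <- function(spec, config, n_subjects = 50L,
                                   seed = 1L, n_restarts = 10L,
                                   priors = default_priors(),
                                   overrides = NULL) {
  stopifnot(n_subjects >= 2)
  cohort <- simulate_cohort(config, spec, params = NULL,
                            n_subjects = n_subjects, seed = seed,
                            priors = priors, overrides = overrides)
  nms <- free_param_names(spec)
  fit_seeds <- local_rng(seed + 1L,
                         sample.int(.Machine$integer.max, n_subjects))
  rows <- list()
  n_failed <- 0L
  for (i in seq_len(n_subjects)) {
    sid <- cohort$params$subject_id[i]
    slog <- cohort$log[cohort$log$subject_id == sid, ]
    fit <- tryCatch(
      fit_map(slog, spec, config, priors = priors,
              n_restarts = n_restarts, seed = fit_seeds[[i]]),
      error = function(e) NULL)
    if (is.null(fit)) {
      n_failed <- n_failed + 1L
      next
    }
    true_theta <- params_to_vector(spec, as_rl_params(cohort$params[i, ]))
    for (nm in nms) {
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = sid, parameter = nm,
        true = unname(true_theta[[nm]]),
        estimated = unname(fit$theta_hat[[nm]]), stringsAsFactors = FALSE)
    }
  }
  report <- do.call(rbind, c(rows, make.row.names = FALSE))
  summary <- do.call(rbind, lapply(nms, function(nm) {
    r <- report[report$parameter == nm, ]
    data.frame(parameter = nm,
               spearman = stats::cor(r$true, r$estimated,
                                     method = "spearman"),
               mae = stats::median(abs(r$true - r$estimated)),
               stringsAsFactors = FALSE)
  }))
  structure(list(report = report, summary = summary,
                 n_subjects = n_subjects, n_failed = n_failed,
                 seed = seed, spec = spec), class = "recovery_report")
}

as_rl_params <- function(row) {
  new_params(alpha1 = row$alpha1, alpha2 = row$alpha2, tau1 = row$tau1,
             tau2 = row$tau2, beta = row$beta, rho = row$rho,
             kappa = row$kappa, bias = row$bias)
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report>", spec_label(x$spec), "-", x$n_subjects,
      "subjects (", x$n_failed, "failed )\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Model recovery at the family level
#'
#' Simulates cohorts from each generating family, fits every candidate
#' family by full MAP, selects per subject by Schwarz weight, and counts
#' selections into a confusion matrix (rows: generating family; columns:
#' selected family).
#'
#' @param gen_specs named list of generating `model_spec`s (the candidate
#'   set fitted to every subject).
#' @param config a `task_config`.
#' @param n_per_family simulated subjects per generating family.
#' @param seed master seed.
#' @param n_restarts restarts per fit.
#' @param priors a `prior_set`.
#' @param overrides optional named list (same names as `gen_specs`) of
#'   parameter overrides for the generating draws, e.g.
#'   `list(pess = list(beta = 0.3))`.
#' @return list with `confusion` (counts matrix), `n_failed` and `seed`.
#' @export
run_model_recovery <- function(gen_specs, config, n_per_family = 25L,
                               seed = 1L, n_restarts = 10L,
                               priors = default_priors(),
                               overrides = NULL) {
  stopifnot(length(gen_specs) >= 2, !is.null(names(gen_specs)))
  fam <- names(gen_specs)
  confusion <- matrix(0L, length(fam), length(fam),
                      dimnames = list(generated = fam, selected = fam))
  n_failed <- 0L
  gen_seeds <- local_rng(seed, sample.int(.Machine$integer.max,
                                          length(fam)))
  for (g in seq_along(fam)) {
    spec_g <- gen_specs[[g]]
    par_list <- draw_params_from_priors(
      spec_g, n_per_family, seed = gen_seeds[[g]], priors = priors,
      overrides = overrides[[fam[g]]])
    sub_seeds <- local_rng(gen_seeds[[g]] %% 100000L + g,
                           sample.int(.Machine$integer.max, n_per_family))
    for (i in seq_len(n_per_family)) {
      cfg_i <- permute_config(config, sub_seeds[[i]])
      slog <- simulate_subject(cfg_i, spec_g, par_list[[i]],
                               subject_id = sprintf("%s_%03d", fam[g], i),
                               seed = sub_seeds[[i]])
      bics <- rep(NA_real_, length(fam))
      kpar <- rep(NA_integer_, length(fam))
      ok <- TRUE
      for (f in seq_along(fam)) {
        fit <- tryCatch(
          fit_map(slog, gen_specs[[f]], config, priors = priors,
                  n_restarts = n_restarts, seed = sub_seeds[[i]] %% 100000L + f),
          error = function(e) NULL)
        if (is.null(fit)) { ok <- FALSE; break }
        bics[f] <- fit$bic
        kpar[f] <- fit$n_params
      }
      if (!ok) {
        n_failed <- n_failed + 1L
        next
      }
      sel <- select_model(data.frame(label = fam, bic = bics,
                                     n_params = kpar,
                                     stringsAsFactors = FALSE))
      confusion[fam[g], sel$selected] <- confusion[fam[g], sel$selected] + 1L
    }
  }
  list(confusion = confusion, n_failed = n_failed, seed = seed)
}
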