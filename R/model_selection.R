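#' BIC Schwarz weights
#'
#' \eqn{w_i = \exp(-\Delta_i/2) / \sum_k \exp(-\Delta_k/2)} with
#' \eqn{\Delta_i = BIC_i - \min_k BIC_k}; interpretable as the probability
#' that model i is the best of the compared set in the BIC sense.
#'
#' @param bics numeric vector of BIC values (finite).
#' @return weights summing to 1, in the input order.
#' @export
schwarz_weights <- function(bics) {
  if (length(bics) == 0) stop("empty BIC list", call. = FALSE)
  if (any(!is.finite(bics))) {
    stop("non-finite BIC values", call. = FALSE)
  }
  delta <- bics - min(bics)
  w <- exp(-delta / 2)
  w / sum(w)
}

#' Select the best model for one subject
#'
#' Pools all fits (typically the 48 specs at both Q-initializations) into
#' one Schwarz-weight computation and selects the maximal-weight entry.
#' Ties are broken toward fewer free parameters, then lexicographic label.
#'
#' @param fits data.frame from [fit_family()] (columns `label`, `bic`,
#'   `n_params` required).
#' @return a `model_comparison`: list with `table` (label, q_init, bic,
#'   delta_bic, weight, selected) and `selected` (the winning label).
#' @export
select_model <- function(fits) {
  need <- c("label", "bic", "n_params")
  missing <- setdiff(need, names(fits))
  if (length(missing) > 0) {
    stop("fits table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  tab <- fits[, intersect(c("label", "q_init", "bic", "n_params"),
                          names(fits)), drop = FALSE]
  tab$delta_bic <- tab$bic - min(tab$bic)
  tab$weight <- schwarz_weights(tab$bic)
  ord <- order(-tab$weight, tab$n_params, tab$label)
  tab$selected <- FALSE
  tab$selected[ord[1]] <- TRUE
  structure(list(table = tab, selected = tab$label[ord[1]]),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("<model_comparison> selected:", x$selected, "\n")
  top <- x$table[order(-x$table$weight), ][seq_len(min(5, nrow(x$table))), ]
  print(top[, c("label", "bic", "delta_bic", "weight")], row.names = FALSE)
  invisible(x)
}

#' Compare the free-choice bonus against a static first-stage bias
#'
#' Supplementary two-model comparison, kept outside the 48-member family:
#' the same base specification fit once with the bonus and once with a
#' static softmax bias on the free option, compared by Schwarz weight.
#'
#' @param log single-subject trial log; @param config its `task_config`.
#' @param base a `model_spec` without bonus or bias; bonus/bias variants
#'   are derived from it.
#' @param ... passed to [fit_map()].
#' @return `model_comparison` over the two variants.
#' @export
compare_bonus_vs_bias <- function(log, config,
                                  base = new_model_spec("q_learning"),
                                  ...) {
  bonus_spec <- base; bonus_spec$has_bonus <- TRUE
  bias_spec <- base; bias_spec$has_static_bias <- TRUE
  f1 <- fit_map(log, bonus_spec, config, ...)
  f2 <- fit_map(log, bias_spec, config, ...)
  fits <- data.frame(
    label = c(spec_label(bonus_spec), spec_label(bias_spec)),
    q_init = c(bonus_spec$q_init, bias_spec$q_init),
    bic = c(f1$bic, f2$bic),
    n_params = c(f1$n_params, f2$n_params), stringsAsFactors = FALSE)
  select_model(fits)
}
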