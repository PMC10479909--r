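#' Descriptive behavioral summaries
#'
#' Summaries computed identically on simulated or human-format trial logs:
#' first-stage free-choice preference, conditional preference given the
#' previous trial, second-stage stay probabilities by reward x coherence,
#' the preference reversal point against the forced reward probability,
#' and the reward-repetition odds ratio. All summaries are deterministic
#' given the log and permutation-invariant over subjects.
#'
#' @name behavior
NULL

#' First-stage free-choice preference
#'
#' @param log trial log (one or more subjects).
#' @return list with `by_subject` (subject x block proportions),
#'   `by_block` (cohort means) and `series` (cohort proportion of free
#'   choices per test-trial index per block).
#' @export
choice_preference <- function(log) {
  test <- log[log$phase == "test", , drop = FALSE]
  if (nrow(test) == 0) stop("log contains no test trials", call. = FALSE)
  test$is_free <- test$stage1_option == "free"
  by_subject <- aggregate(is_free ~ subject_id + block_index, test, mean)
  names(by_subject)[names(by_subject) == "is_free"] <- "pref"
  n <- aggregate(is_free ~ subject_id + block_index, test, length)
  by_subject$n_test <- n$is_free
  by_block <- aggregate(pref ~ block_index, by_subject, mean)
  names(by_block)[names(by_block) == "pref"] <- "mean_pref"
  by_block$n_subjects <- aggregate(pref ~ block_index, by_subject,
                                   length)$pref
  series <- aggregate(is_free ~ block_index + trial_index, test, mean)
  names(series)[names(series) == "is_free"] <- "prop_free"
  series <- series[order(series$block_index, series$trial_index), ]
  rownames(series) <- NULL
  structure(list(by_subject = by_subject, by_block = by_block,
                 series = series), class = "preference_summary")
}

#' Centered 2-point moving average of a preference series
#'
#' @param x numeric series.
#' @return smoothed series (endpoints kept as-is).
#' @export
smooth_series <- function(x) {
  if (length(x) < 2) return(x)
  out <- x
  out[-1] <- (x[-1] + x[-length(x)]) / 2
  out
}

#' First-stage preference conditional on the previous test trial
#'
#' P(free | previous free) and P(free | previous forced) per subject and
#' block; the first test trial of each block has no predecessor and is
#' excluded.
#'
#' @param log trial log.
#' @return data.frame with the two conditional proportions and their
#'   trial counts (NA where a condition never occurred).
#' @export
conditional_stage1_preference <- function(log) {
  test <- log[log$phase == "test", , drop = FALSE]
  if (nrow(test) == 0) stop("log contains no test trials", call. = FALSE)
  out <- list()
  for (sid in unique(test$subject_id)) {
    for (blk in unique(test$block_index[test$subject_id == sid])) {
      tb <- test[test$subject_id == sid & test$block_index == blk, ]
      tb <- tb[order(tb$trial_index), ]
      if (nrow(tb) < 2) next
      cur <- tb$stage1_option[-1] == "free"
      prev <- tb$stage1_option[-nrow(tb)] == "free"
      out[[length(out) + 1L]] <- data.frame(
        subject_id = sid, block_index = blk,
        p_free_given_free = if (any(prev)) mean(cur[prev]) else NA_real_,
        n_given_free = sum(prev),
        p_free_given_forced = if (any(!prev)) mean(cur[!prev]) else NA_real_,
        n_given_forced = sum(!prev), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Second-stage stay probabilities by reward x coherence
#'
#' For each pair of successive free-option trials within a block (the
#' conditioning trial is the most recent free trial; intervening forced
#' trials are allowed), the earlier trial is classified into the 2x2 cell
#' {rewarded, unrewarded} x {coherent, incoherent}, and "stay" means the
#' later emitted second-stage action equals the earlier *emitted* action
#' (not the displayed, possibly swapped, target).
#'
#' @param log trial log (incoherence-task format; works on any log, with
#'   the incoherent cells empty when coherence is never broken).
#' @param phases phases whose free trials enter the pairing.
#' @return data.frame per subject: `stay_<cell>` proportions and
#'   `n_<cell>` counts, cells `rc`, `ru`, `ic`, `iu` (reward/unrewarded x
#'   coherent/incoherent: `rc` = rewarded & coherent, `iu` = unrewarded &
#'   incoherent). Empty cells are NA.
#' @export
stay_probabilities <- function(log, phases = c("train", "test")) {
  free <- log[log$stage1_option == "free" & log$phase %in% phases, ,
              drop = FALSE]
  cells <- c("rc", "ru", "ic", "iu")
  out <- list()
  for (sid in unique(log$subject_id)) {
    stays <- stats::setNames(rep(0, 4), cells)
    ns <- stats::setNames(rep(0, 4), cells)
    for (blk in unique(free$block_index[free$subject_id == sid])) {
      fb <- free[free$subject_id == sid & free$block_index == blk, ]
      fb <- fb[order(match(fb$phase, c("train", "test")), fb$trial_index), ]
      if (nrow(fb) < 2) next
      for (i in seq_len(nrow(fb) - 1L)) {
        cell <- if (fb$coherent[i]) {
          if (fb$reward[i] == 1) "rc" else "ru"
        } else {
          if (fb$reward[i] == 1) "ic" else "iu"
        }
        stay <- fb$stage2_action[i + 1L] == fb$stage2_action[i]
        stays[cell] <- stays[cell] + stay
        ns[cell] <- ns[cell] + 1
      }
    }
    row <- data.frame(subject_id = sid, stringsAsFactors = FALSE)
    for (cell in cells) {
      row[[paste0("stay_", cell)]] <-
        if (ns[cell] > 0) stays[cell] / ns[cell] else NA_real_
      row[[paste0("n_", cell)]] <- ns[cell]
    }
    out[[length(out) + 1L]] <- row
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Preference reversal point against the forced reward probability
#'
#' Logistic interpolation of per-subject block preferences against
#' p_forced; returns the probability at which the cohort is indifferent
#' (free-choice proportion 0.5). This is a descriptive approximation to a
#' smooth population fit, not an inferential estimate.
#'
#' @param block_prefs data.frame with columns `p_forced` and `pref`
#'   (free-choice proportion, one row per subject x block).
#' @return the estimated crossing (scalar), or NA with a `"reason"`
#'   attribute when preferences are degenerate or the crossing falls
#'   outside \[0, 1\].
#' @export
reversal_point <- function(block_prefs) {
  stopifnot(all(c("p_forced", "pref") %in% names(block_prefs)))
  if (length(unique(block_prefs$p_forced)) < 2) {
    stop("need at least two distinct p_forced levels", call. = FALSE)
  }
  if (stats::var(block_prefs$pref) == 0) {
    return(structure(NA_real_, reason = "constant preferences"))
  }
  fit <- stats::glm(pref ~ p_forced, family = stats::quasibinomial(),
                    data = block_prefs)
  b <- stats::coef(fit)
  if (!is.finite(b[2]) || b[2] == 0) {
    return(structure(NA_real_, reason = "flat logistic fit"))
  }
  crossing <- unname(-b[1] / b[2])
  if (crossing < 0 || crossing > 1) {
    return(structure(NA_real_, reason = "no crossing in [0, 1]"))
  }
  crossing
}

#' Odds ratio of repeating the first-stage choice after reward
#'
#' 2x2 contingency of previous-trial reward against repetition of the
#' previous first-stage selection, pooled over subjects and blocks within
#' the test phase; the odds ratio uses the Haldane-Anscombe 0.5 correction
#' when any cell is zero.
#'
#' @param log trial log.
#' @return list with `odds_ratio` and the 2x2 `table` (rows: previous
#'   rewarded yes/no; columns: repeated yes/no).
#' @export
reward_repetition_effect <- function(log) {
  test <- log[log$phase == "test", , drop = FALSE]
  if (nrow(test) == 0) stop("log contains no test trials", call. = FALSE)
  tab <- matrix(0, 2, 2,
                dimnames = list(prev_rewarded = c("yes", "no"),
                                repeated = c("yes", "no")))
  for (sid in unique(test$subject_id)) {
    for (blk in unique(test$block_index[test$subject_id == sid])) {
      tb <- test[test$subject_id == sid & test$block_index == blk, ]
      tb <- tb[order(tb$trial_index), ]
      if (nrow(tb) < 2) next
      prev_r <- tb$reward[-nrow(tb)] == 1
      rep1 <- tb$stage1_option[-1] == tb$stage1_option[-nrow(tb)]
      tab["yes", "yes"] <- tab["yes", "yes"] + sum(prev_r & rep1)
      tab["yes", "no"] <- tab["yes", "no"] + sum(prev_r & !rep1)
      tab["no", "yes"] <- tab["no", "yes"] + sum(!prev_r & rep1)
      tab["no", "no"] <- tab["no", "no"] + sum(!prev_r & !rep1)
    }
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(list(odds_ratio = structure(NA_real_,
                                       reason = "zero margin"),
                table = tab))
  }
  t2 <- if (any(tab == 0)) tab + 0.5 else tab
  or <- (t2["yes", "yes"] * t2["no", "no"]) /
        (t2["yes", "no"] * t2["no", "yes"])
  list(odds_ratio = unname(or), table = tab)
}
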