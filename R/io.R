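#' Trial-log files
#'
#' Trial logs are plain CSV (UTF-8, '.' decimal), one row per trial with
#' the canonical header, rows in chronological order per subject; trial
#' indices are 0-based within phase.
#'
#' @name trial_io
NULL

#' Write a trial log to CSV
#'
#' @param log trial-log data.frame.
#' @param path output file.
#' @export
write_trial_log <- function(log, path) {
  missing <- setdiff(TRIAL_LOG_COLUMNS, names(log))
  if (length(missing) > 0) {
    stop("trial log lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  utils::write.csv(log[, TRIAL_LOG_COLUMNS], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read and validate a trial log
#'
#' Checks the canonical header, the enumerated fields, and the internal
#' consistency `coherent == (stage2_action == displayed_target)`;
#' violations are reported with their row number.
#'
#' @param path CSV file written by [write_trial_log()] (or human data in
#'   the same schema).
#' @return validated trial-log data.frame.
#' @export
read_trial_log <- function(path) {
  log <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(TRIAL_LOG_COLUMNS, names(log))
  if (length(missing) > 0) {
    stop("trial log lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(log) == 0) return(empty_trial_log())
  log$stage1_is_choice <- as.logical(log$stage1_is_choice)
  log$coherent <- as.logical(log$coherent)
  check_enum <- function(col, allowed) {
    bad <- which(!log[[col]] %in% allowed)
    if (length(bad) > 0) {
      stop("invalid ", col, " at row ", bad[1], ": '", log[[col]][bad[1]],
           "'", call. = FALSE)
    }
  }
  check_enum("phase", c("train", "test"))
  check_enum("stage1_option", c("free", "forced"))
  check_enum("stage2_action", c("a1", "a2"))
  check_enum("displayed_target", c("a1", "a2"))
  check_enum("reward", c(0L, 1L))
  bad <- which(log$coherent != (log$stage2_action == log$displayed_target))
  if (length(bad) > 0) {
    stop("coherent flag inconsistent with displayed target at row ",
         bad[1], call. = FALSE)
  }
  bad <- which(log$phase == "train" & log$stage1_is_choice)
  if (length(bad) > 0) {
    stop("training trial marked as a stage-1 choice at row ", bad[1],
         call. = FALSE)
  }
  log
}

#' Write / read a cohort's generating-parameter table
#'
#' Sidecar CSV accompanying a simulated cohort's trial log.
#'
#' @param params data.frame from [simulate_cohort()].
#' @param path file path.
#' @export
write_params_table <- function(params, path) {
  utils::write.csv(params, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_params_table
#' @export
read_params_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
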