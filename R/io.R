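# Tab-delimited trial-table dialect shared by simulation and real-data
# ingestion, plus the exclusion report and JSON summaries.

TRIAL_COLUMNS <- c("participant", "trial_index", "run", "condition",
                   "n_shown", "peer_confidence", "true_pct", "is_filler",
                   "e1", "p", "e2", "missed")

#' Write a trial table
#'
#' One row per trial, tab-delimited with a header. The canonical columns
#' are `participant`, `trial_index`, `run`, `condition` (uncertain/certain),
#' `n_shown`, `peer_confidence` (1..3), `true_pct`, `is_filler`, `e1`, `p`,
#' `e2` and `missed`; derived columns (`s`, `included`,
#' `exclusion_reason`) are written when present.
#'
#' @param records Trial records.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_trials <- function(records, path) {
  keep <- c(intersect(TRIAL_COLUMNS, names(records)),
            intersect(c("blue_count", "s", "included", "exclusion_reason"),
                      names(records)))
  utils::write.table(records[, keep], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a trial table
#'
#' Reads the dialect written by [write_trials()]; also used to ingest real
#' behavioral data exported in the same format. Non-integer estimates are
#' rounded to the integer percentage grid (with a message reporting how
#' many were affected).
#'
#' @param path Input file path.
#' @return Data frame of trial records.
#' @export
read_trials <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(TRIAL_COLUMNS, names(d))
  if (length(missing))
    stop("trial table lacks columns: ", paste(missing, collapse = ", "))
  for (col in c("e1", "p", "e2")) {
    rounded <- round(d[[col]])
    n_off <- sum(abs(d[[col]] - rounded) > 1e-9, na.rm = TRUE)
    if (n_off > 0)
      message(n_off, " non-integer ", col, " values rounded to the grid")
    d[[col]] <- as.integer(rounded)
  }
  d$is_filler <- as.logical(d$is_filler)
  d$missed <- as.logical(d$missed)
  d
}

#' Write the per-reason exclusion report
#'
#' @param records Records after [apply_trial_filters()].
#' @param path Output file path (tab-delimited).
#' @return Invisibly, the report data frame (`reason`, `n_trials`).
#' @export
write_exclusion_report <- function(records, path) {
  tab <- table(records$exclusion_reason)
  report <- data.frame(reason = names(tab), n_trials = as.integer(tab))
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(report)
}

#' Write a regression summary as JSON
#'
#' @param result A [fit_condition_regression()] result.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_regression_json <- function(result, path) {
  jsonlite::write_json(
    list(fixed = result$fixed,
         ranef_variances = result$ranef_variances,
         n_participants = result$n_participants,
         n_trials = result$n_trials,
         formula = result$formula,
         structure_used = result$structure_used,
         fallbacks = result$fallbacks),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
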