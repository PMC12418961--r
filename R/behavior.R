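# Model-free analysis: social information use, exclusion rules, and the
# condition-effects mixed regression.

EXCLUSION_LEVELS <- c("none", "filler", "missed", "no_peer",
                      "outlier_3sd", "s_out_of_range")

#' Social information use
#'
#' The fraction of the distance from the first estimate to the peer's
#' estimate that the second estimate covers:
#' `s = (e2 - e1) / (p - e1)`. 0 means the peer was ignored, 1 means the
#' peer's estimate was copied; values outside \[0, 1\] are possible and are
#' flagged downstream.
#'
#' @param e1,e2,p First estimate, second estimate and peer estimate, in
#'   percent. Vectorised.
#' @return Numeric vector; `NA` where `p == e1` (s is undefined there and
#'   such trials are excluded as `no_peer`).
#' @examples
#' social_info_use(40, 48, 56)  # 0.5
#' @export
social_info_use <- function(e1, e2, p) {
  ifelse(p == e1, NA_real_, (e2 - e1) / (p - e1))
}

#' Apply the trial-level exclusion rules
#'
#' Assigns each trial an exclusion reason with precedence
#' filler > missed > no_peer > outlier_3sd > s_out_of_range:
#' * `filler`: catch trials with peer estimates very near or very far.
#' * `missed`: no response at either estimation phase.
#' * `no_peer`: the peer estimate equals the first estimate, leaving `s`
#'   undefined.
#' * `outlier_3sd`: the first or second estimate deviates more than 3 SD
#'   from the cohort mean of its (condition x true percentage) cell,
#'   computed over non-filler, non-missed trials of the full cohort.
#' * `s_out_of_range`: `s` outside \[0, 1\], i.e. the second estimate is not
#'   a weighted average of the first and the peer's estimate.
#'
#' @param records Trial records of one or more participants.
#' @param group_stats Optional precomputed cell statistics from
#'   [cell_stats()]; computed from `records` when omitted.
#' @return The records with columns `s`, `included` and `exclusion_reason`
#'   set. Re-applying the filters is a no-op.
#' @export
apply_trial_filters <- function(records, group_stats = NULL) {
  if (nrow(records) == 0L) stop("empty cohort")
  if (is.null(records$missed)) records$missed <- FALSE
  if (is.null(group_stats)) group_stats <- cell_stats(records)
  records$s <- social_info_use(records$e1, records$e2, records$p)

  key <- paste(records$condition, records$true_pct)
  st <- group_stats[match(key, group_stats$key), ]
  out1 <- abs(records$e1 - st$mean_e1) > 3 * st$sd_e1
  out2 <- abs(records$e2 - st$mean_e2) > 3 * st$sd_e2
  outlier <- !is.na(out1) & !is.na(out2) & (out1 | out2)

  reason <- rep("none", nrow(records))
  reason[!is.na(records$s) & (records$s < 0 | records$s > 1)] <- "s_out_of_range"
  reason[outlier] <- "outlier_3sd"
  reason[is.na(records$s)] <- "no_peer"
  reason[records$missed] <- "missed"
  reason[records$is_filler] <- "filler"

  records$exclusion_reason <- factor(reason, levels = EXCLUSION_LEVELS)
  records$included <- reason == "none"
  records
}

#' Per-cell cohort statistics for the 3-SD outlier rule
#'
#' Mean and SD of the first and second estimates per (condition x true
#' percentage) cell, over non-filler, non-missed trials of the cohort.
#'
#' @param records Trial records of the full ingested cohort.
#' @return Data frame with one row per cell (`key`, `mean_e1`, `sd_e1`,
#'   `mean_e2`, `sd_e2`).
#' @export
cell_stats <- function(records) {
  if (is.null(records$missed)) records$missed <- FALSE
  d <- records[!records$is_filler & !records$missed, ]
  key <- paste(d$condition, d$true_pct)
  agg <- function(x, f) tapply(x, key, f)
  cells <- sort(unique(key))
  data.frame(key = cells,
             mean_e1 = as.numeric(agg(d$e1, mean)[cells]),
             sd_e1 = as.numeric(agg(d$e1, stats::sd)[cells]),
             mean_e2 = as.numeric(agg(d$e2, mean)[cells]),
             sd_e2 = as.numeric(agg(d$e2, stats::sd)[cells]),
             stringsAsFactors = FALSE)
}

#' Apply the participant-level exclusion rule
#'
#' Removes participants whose social information use is exactly 0 on more
#' than 70% of their evaluable non-filler trials (too little variation to
#' analyse), plus any participants flagged manually (e.g. after qualitative
#' inspection of task understanding).
#'
#' @param records Filtered trial records (see [apply_trial_filters()]).
#' @param manual_exclusions Character vector of participant ids to drop
#'   regardless of the stay criterion.
#' @return List with `records` (retained participants' trials) and `log`
#'   (data frame per participant: stay proportion, n evaluable trials,
#'   retained flag, reason).
#' @export
apply_participant_filters <- function(records, manual_exclusions = character()) {
  ev <- records[!records$is_filler & !is.na(records$s) & !records$missed, ]
  stay <- tapply(ev$s == 0, ev$participant, mean)
  n_ev <- tapply(ev$s, ev$participant, length)
  ids <- names(stay)
  reason <- rep("retained", length(ids))
  reason[stay > 0.70] <- "stay_above_70pct"
  reason[ids %in% manual_exclusions] <- "manual"
  log <- data.frame(participant = ids,
                    n_evaluable = as.integer(n_ev),
                    stay_proportion = as.numeric(stay),
                    retained = reason == "retained",
                    reason = reason,
                    stringsAsFactors = FALSE)
  rownames(log) <- NULL
  keep <- log$participant[log$retained]
  list(records = records[records$participant %in% keep, ], log = log)
}

#' Mixed-effects regression of social information use on the task factors
#'
#' Fits `s ~ certainty * confidence` with by-participant random intercepts
#' and slopes, on included trials only. Peer confidence is coded -1 / 0 / +1
#' (low / medium / high); own certainty is coded -0.5 (uncertain) / +0.5
#' (certain) by default, giving a unit contrast between conditions. If the
#' maximal random-effects structure is singular or fails to converge, the
#' model falls back to uncorrelated slopes and then to a random intercept
#' only, logging each step.
#'
#' @param records Filtered trial records with an `included` column.
#' @param certainty_coding Length-2 numeric, codes for (uncertain, certain).
#' @return List of class `socbayes_regression`: `fixed` (estimate, SE,
#'   df, t, p per term), `ranef_variances`, `n_participants`, `n_trials`,
#'   `formula`, `fallbacks` (character log), and the fitted `lmerMod` in
#'   `$fit`.
#' @export
fit_condition_regression <- function(records, certainty_coding = c(-0.5, 0.5)) {
  d <- records[records$included & !is.na(records$s), ]
  if (length(unique(d$participant)) < 2L)
    stop("need included trials from at least 2 participants")
  d$certainty_c <- ifelse(d$condition == "certain",
                          certainty_coding[2], certainty_coding[1])
  d$confidence_c <- d$peer_confidence - 2

  forms <- list(
    maximal = s ~ certainty_c * confidence_c +
      (1 + certainty_c * confidence_c | participant),
    uncorrelated = s ~ certainty_c * confidence_c +
      (1 + certainty_c * confidence_c || participant),
    intercept_only = s ~ certainty_c * confidence_c + (1 | participant))

  fallbacks <- character()
  fit <- NULL
  used <- NULL
  for (nm in names(forms)) {
    cand <- tryCatch(
      suppressWarnings(suppressMessages(
        lmerTest::lmer(forms[[nm]], data = d,
                       control = lme4::lmerControl(calc.derivs = FALSE)))),
      error = function(e) e)
    if (inherits(cand, "error")) {
      fallbacks <- c(fallbacks, sprintf("%s: error (%s)", nm,
                                        conditionMessage(cand)))
      next
    }
    if (lme4::isSingular(cand, tol = 1e-4)) {
      fallbacks <- c(fallbacks, sprintf("%s: singular fit", nm))
      if (is.null(fit)) { fit <- cand; used <- nm }  # keep as last resort
      next
    }
    fit <- cand; used <- nm
    break
  }
  if (is.null(fit)) stop("mixed regression failed to converge: ",
                         paste(fallbacks, collapse = "; "))

  sm <- summary(fit)$coefficients
  fixed <- data.frame(term = rownames(sm),
                      estimate = sm[, "Estimate"],
                      se = sm[, "Std. Error"],
                      df = sm[, "df"],
                      t = sm[, "t value"],
                      p = sm[, "Pr(>|t|)"],
                      stringsAsFactors = FALSE)
  rownames(fixed) <- NULL
  vc <- as.data.frame(lme4::VarCorr(fit))

  structure(list(fixed = fixed,
                 ranef_variances = vc,
                 n_participants = length(unique(d$participant)),
                 n_trials = nrow(d),
                 formula = deparse1(forms[[used]]),
                 structure_used = used,
                 fallbacks = fallbacks,
                 fit = fit),
            class = "socbayes_regression")
}

#' @export
print.socbayes_regression <- function(x, ...) {
  cat(sprintf("Mixed regression of social information use (%d participants, %d trials)\n",
              x$n_participants, x$n_trials))
  cat("Random-effects structure:", x$structure_used, "\n")
  if (length(x$fallbacks))
    cat("Fallbacks:", paste(x$fallbacks, collapse = "; "), "\n")
  print(x$fixed, digits = 3)
  invisible(x)
}
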