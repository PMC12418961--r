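# Model-based trial-level regressors for event-related fMRI designs:
# own certainty, peer confidence, the Kullback-Leibler belief update, and
# the confidence-modulated stay bias, exported as 3-column event files.
#
# GLM estimation itself is out of scope; this module only constructs the
# trial-level quantities and writes them in the standard
# onset/duration/amplitude text format.

#' Model-based own certainty of one or more trials
#'
#' The number of mushrooms shown multiplied by the fitted condition-specific
#' distortion parameter: `n_shown * alpha_uncertain` in the uncertain
#' condition, `n_shown * alpha_certain` in the certain condition.
#'
#' @param trials Trial records with columns `condition` and `n_shown`.
#' @param params Fitted parameters of a dual-alpha model (e.g. M3d).
#' @return Numeric vector of perceived counts.
#' @examples
#' model_based_certainty(data.frame(condition = "uncertain", n_shown = 5),
#'                       c(alpha_uncertain = 28, alpha_certain = 4))  # 140
#' @export
model_based_certainty <- function(trials, params) {
  stopifnot(all(c("alpha_uncertain", "alpha_certain") %in% names(params)))
  trials$n_shown * ifelse(trials$condition == "uncertain",
                          params[["alpha_uncertain"]],
                          params[["alpha_certain"]])
}

#' Model-based peer confidence of one or more trials
#'
#' The number of observations credited to the peer under the linear
#' confidence weighting: `theta_ic + theta_slope * (confidence - 1)` with
#' confidence coded 1 = low, 2 = medium, 3 = high. Defined for non-filler
#' trials only (filler peers are constructed to be implausible).
#'
#' @param trials Trial records with columns `peer_confidence` and
#'   `is_filler`.
#' @param params Fitted parameters containing `theta_ic` and `theta_slope`.
#' @return Numeric vector of peer counts.
#' @export
model_based_peer_confidence <- function(trials, params) {
  stopifnot(all(c("theta_ic", "theta_slope") %in% names(params)))
  if (any(trials$is_filler))
    stop("peer-confidence regressor is defined on non-filler trials only")
  params[["theta_ic"]] + params[["theta_slope"]] * (trials$peer_confidence - 1)
}

#' Kullback-Leibler divergence of the belief update
#'
#' Quantifies how much the belief distribution changed from the first to the
#' second estimate, capturing both the shift of the point estimate and the
#' change in distribution width. The first-estimate belief is the beta
#' distribution with counts from `e1` and the model-based perceived count;
#' the second-estimate belief takes its point estimate from the observed
#' `e2` and its precision from the model-based total count (perceived plus
#' peer observations). Both are discretised on the 101-point response grid,
#' clipped at `clip` and renormalised, and the divergence of the updated
#' belief from the prior belief, `KL(post || prior)`, is returned in nats.
#'
#' @param trials Non-filler trial records with `e1`, `e2`, `condition`,
#'   `n_shown`, `peer_confidence`.
#' @param params Fitted parameters of a dual-alpha, linear-theta model.
#' @param clip Probability floor applied before renormalisation.
#' @return Nonnegative numeric vector, one divergence per trial. Strictly
#'   positive whenever the peer contributes observations, even for stay
#'   responses, because the updated belief is narrower.
#' @export
kl_update <- function(trials, params, clip = 1e-10) {
  npv <- perceived_n("M3d", params, trials$condition, trials$n_shown)
  npeer <- peer_n("M3d", params, trials$peer_confidence)
  prior <- e1_counts(trials$e1, npv)
  post <- e1_counts(trials$e2, npv + npeer)
  p_prior <- clip_renorm(response_pmf(prior$blue, prior$red), clip)
  p_post <- clip_renorm(response_pmf(post$blue, post$red), clip)
  rowSums(p_post * (log(p_post) - log(p_prior)))
}

clip_renorm <- function(p, clip) {
  p <- pmax(p, clip)
  p / rowSums(p)
}

#' Confidence-modulated stay-bias regressor
#'
#' The trial-wise stay mass `beta ^ confidence` implied by the
#' exponential-stay model, used as a supplementary parametric modulator.
#'
#' @inheritParams model_based_peer_confidence
#' @param params Fitted parameters containing `beta`.
#' @return Numeric vector in (0, 1).
#' @export
stay_bias_regressor <- function(trials, params) {
  stopifnot("beta" %in% names(params))
  params[["beta"]] ^ trials$peer_confidence
}

#' Build the full set of trial-level parametric regressors
#'
#' Computes, for each trial, model-based own certainty (all trials, at the
#' first-estimate prompt, 0.5 s), model-based peer confidence, the KL belief
#' update and the stay-bias modulator (non-filler trials only, at the
#' social-information onset, 4 s), and mean-centres each regressor within
#' each run over the trials entering it.
#'
#' If the records carry no `e1_onset` / `social_onset` columns, a synthetic
#' event schedule is generated: trials are laid out in run order with a
#' fixed trial spacing so that exported files are well-formed for simulated
#' cohorts.
#'
#' @param records One participant's trial records.
#' @param params Fitted parameters of the winning model (dual alpha, linear
#'   theta, stay bias).
#' @param trial_spacing Seconds between consecutive trial onsets of the
#'   synthetic schedule.
#' @return Data frame of class `socbayes_regressors`: per trial, the run,
#'   filler flag, onsets, raw and mean-centred regressor values (centred
#'   columns suffixed `_c`; `NA` on trials not entering a regressor).
#' @export
build_regressors <- function(records, params, trial_spacing = 24) {
  rec <- records[order(records$run, records$trial_index), ]
  if (is.null(rec$e1_onset) || is.null(rec$social_onset)) {
    within_run <- stats::ave(seq_len(nrow(rec)), rec$run, FUN = seq_along)
    rec$e1_onset <- (within_run - 1) * trial_spacing + 8
    rec$social_onset <- rec$e1_onset + 6
  }
  out <- data.frame(participant = rec$participant,
                    run = rec$run,
                    trial_index = rec$trial_index,
                    is_filler = rec$is_filler,
                    e1_onset = rec$e1_onset,
                    social_onset = rec$social_onset,
                    stringsAsFactors = FALSE)
  out$certainty <- model_based_certainty(rec, params)
  nf <- !rec$is_filler
  out$peer_confidence_reg <- NA_real_
  out$kl <- NA_real_
  out$stay_bias <- NA_real_
  out$peer_confidence_reg[nf] <-
    model_based_peer_confidence(rec[nf, ], params)
  out$kl[nf] <- kl_update(rec[nf, ], params)
  out$stay_bias[nf] <- stay_bias_regressor(rec[nf, ], params)

  for (v in c("certainty", "peer_confidence_reg", "kl", "stay_bias")) {
    out[[paste0(v, "_c")]] <-
      out[[v]] - stats::ave(out[[v]], out$run,
                            FUN = function(x) mean(x, na.rm = TRUE))
  }
  class(out) <- c("socbayes_regressors", "data.frame")
  out
}

#' Export a regressor as 3-column event files
#'
#' Writes one tab-delimited text file per run, with columns onset (s),
#' duration (s) and the mean-centred regressor value, all formatted with 6
#' decimals. The certainty regressor is timed to the first 500 ms of the
#' first-estimate prompt; peer confidence, KL and stay bias span the 4 s of
#' the social-information display and include non-filler trials only.
#'
#' @param regressors A [build_regressors()] data frame.
#' @param which One of `"certainty"`, `"peer_confidence_reg"`, `"kl"`,
#'   `"stay_bias"`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written, named
#'   `<participant>_<run>_<which>.txt`.
#' @export
export_events <- function(regressors, which = c("certainty",
                                                "peer_confidence_reg",
                                                "kl", "stay_bias"),
                          dir = ".") {
  which <- match.arg(which)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  at_e1 <- which == "certainty"
  val <- regressors[[paste0(which, "_c")]]
  keep <- !is.na(val)
  reg <- regressors[keep, ]
  val <- val[keep]
  onset <- if (at_e1) reg$e1_onset else reg$social_onset
  duration <- if (at_e1) 0.5 else 4.0
  paths <- character(0)
  for (r in sort(unique(reg$run))) {
    i <- reg$run == r
    path <- file.path(dir, sprintf("%s_%d_%s.txt",
                                   reg$participant[1], r, which))
    lines <- sprintf("%.6f\t%.6f\t%.6f", onset[i], duration, val[i])
    writeLines(lines, path)
    paths <- c(paths, path)
  }
  invisible(paths)
}
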