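# Simulation of participants from any model in the family.

#' Default parameter ranges for simulation studies
#'
#' The observed parameter ranges of the original cohorts are not published,
#' so recovery simulations draw from ranges chosen to bracket the reported
#' median estimates (alpha medians 4-29, peer counts 55-241) while staying
#' inside the fitting bounds: alpha in \[1, 50\], theta intercept and slope
#' in \[1, 150\], level-specific or single theta in \[1, 300\], stay bias in
#' \[0.05, 0.9\].
#'
#' @param spec A `socbayes_model` or model name.
#' @return Named list of `c(lower, upper)` ranges, one per free parameter.
#' @export
default_sim_ranges <- function(spec) {
  spec <- as_model_spec(spec)
  rng <- list()
  for (p in spec$par_names) {
    rng[[p]] <-
      if (startsWith(p, "alpha")) c(1, 50)
      else if (p %in% c("theta_ic", "theta_slope")) c(1, 150)
      else if (startsWith(p, "theta")) c(1, 300)
      else c(0.05, 0.9)
  }
  rng
}

#' Draw random parameter vectors for a model
#'
#' Each parameter is drawn independently and uniformly from its range;
#' ranges must lie within the model's fitting bounds.
#'
#' @param spec A `socbayes_model` or model name.
#' @param n Number of parameter vectors to draw.
#' @param ranges Named list of `c(lower, upper)` per parameter; defaults to
#'   [default_sim_ranges()].
#' @param seed Integer seed.
#' @return List of `n` named parameter vectors.
#' @export
sample_parameters <- function(spec, n, ranges = NULL, seed = 1L) {
  spec <- as_model_spec(spec)
  if (is.null(ranges)) ranges <- default_sim_ranges(spec)
  if (!setequal(names(ranges), spec$par_names))
    stop("ranges must cover exactly: ", paste(spec$par_names, collapse = ", "))
  for (p in spec$par_names) {
    r <- ranges[[p]]
    b <- spec$bounds[[p]]
    if (length(r) != 2 || r[1] > r[2]) stop("empty or inverted range for ", p)
    if (r[1] < b[1] || r[2] > b[2])
      stop("range for ", p, " outside fitting bounds")
  }
  set.seed(as.integer(seed))
  lapply(seq_len(n), function(i) {
    vapply(spec$par_names, function(p)
      stats::runif(1, ranges[[p]][1], ranges[[p]][2]), numeric(1))
  })
}

#' Simulate one participant's trial records from a model
#'
#' For each trial of the design the mushroom fields are sampled
#' ([sample_fields()]), the peer's estimate is drawn under the 15-18 point
#' distance rule ([sample_peer()]), and the second estimate is drawn from
#' the model's full response distribution (stay mass on `e1` plus the
#' discrete posterior pmf, [trial_response_probs()]).
#'
#' @param design A design from [generate_design()].
#' @param spec A `socbayes_model` or model name.
#' @param params Named parameter vector within the model's bounds.
#' @param seed Integer seed; the full record set is reproducible from it.
#' @param participant Participant identifier stored in the records.
#' @return Data frame of trial records: the design columns plus
#'   `participant`, `blue_count`, `e1`, `p`, `e2`, `missed`, and `s` (the
#'   realised social information use, `NA` where `p == e1`). The generating
#'   parameters are attached as attribute `"true_params"`.
#' @export
simulate_participant <- function(design, spec, params, seed = 1L,
                                 participant = "sim01") {
  spec <- as_model_spec(spec)
  check_params(spec, params)
  set.seed(as.integer(seed))
  rec <- as.data.frame(design)
  n <- nrow(rec)
  fields <- sample_fields(rec$true_pct, rec$n_shown)
  rec$blue_count <- fields$blue_count
  rec$e1 <- fields$e1
  rec$p <- sample_peer(rec$e1, rec$true_pct, rec$is_filler)
  probs <- trial_response_probs(rec, spec, params)
  rec$e2 <- vapply(seq_len(n), function(i)
    sample(0:100, 1L, prob = probs[i, ]), integer(1))
  rec$missed <- FALSE
  rec$s <- social_info_use(rec$e1, rec$e2, rec$p)
  rec <- cbind(participant = participant, rec)
  attr(rec, "true_params") <- params
  attr(rec, "model") <- spec$name
  rec
}

#' Simulate a cohort of participants
#'
#' Each participant gets a freshly randomised design (same experiment) and
#' an independent set of field, peer and response draws; all randomness
#' derives from `seed`.
#'
#' @param n_participants Cohort size.
#' @param spec A `socbayes_model` or model name.
#' @param params_list Either a single named parameter vector (shared by all
#'   participants) or a list of length `n_participants`.
#' @param experiment 1 or 2; selects the task design.
#' @param seed Integer seed.
#' @return Data frame of stacked trial records; the per-participant
#'   generating parameters are attached as attribute `"true_params"` (a
#'   named list).
#' @export
simulate_cohort <- function(n_participants, spec, params_list,
                            experiment = 2L, seed = 1L) {
  spec <- as_model_spec(spec)
  if (!is.list(params_list))
    params_list <- rep(list(params_list), n_participants)
  stopifnot(length(params_list) == n_participants)
  set.seed(as.integer(seed))
  sub_seeds <- sample.int(.Machine$integer.max - 1L, 2L * n_participants)
  ids <- sprintf("sim%03d", seq_len(n_participants))
  recs <- lapply(seq_len(n_participants), function(i) {
    d <- generate_design(experiment, seed = sub_seeds[2 * i - 1])
    simulate_participant(d, spec, params_list[[i]],
                         seed = sub_seeds[2 * i], participant = ids[i])
  })
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  attr(out, "true_params") <- stats::setNames(params_list, ids)
  attr(out, "model") <- spec$name
  out
}
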