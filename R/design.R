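# Synthetic task designs for the mushroom estimation game.
#
# Experiment 1 (online): 42 main trials crossing own certainty (5 vs 45
# mushrooms shown) x peer confidence (low/medium/high) x 7 true percentages,
# plus 12 filler trials, played in 3 rounds.
# Experiment 2 (scanner): 60 main trials (5 true percentages, each cell
# twice) plus 15 filler trials, pseudo-randomly split over 3 runs.

TRUE_PCT_EXP1 <- c(12.5, 25, 37.5, 50, 62.5, 75, 87.5)
TRUE_PCT_EXP2 <- c(12.5, 25, 37.5, 62.5, 75)

#' Generate a full factorial task design
#'
#' Builds the complete trial list for one experiment: every combination of
#' own-certainty condition (uncertain = 5 mushrooms shown, certain = 45),
#' peer confidence level (1..3) and true blue-mushroom percentage, repeated
#' the experiment's number of times, plus the experiment's filler trials.
#' Filler trials draw an arbitrary integer true percentage in 0..100 and are
#' balanced over conditions and confidence levels. Trial order is randomised
#' by `seed`, and trials are split over 3 runs balanced on condition and
#' filler status.
#'
#' @param experiment 1 (42 main + 12 filler trials) or 2 (60 main + 15
#'   filler trials).
#' @param seed Integer seed controlling trial order, run assignment and
#'   filler percentages.
#' @return A data frame of class `socbayes_design` with columns
#'   `trial_index`, `run`, `condition`, `n_shown`, `peer_confidence`,
#'   `true_pct`, `is_filler`, and attribute `experiment`.
#' @examples
#' d <- generate_design(1, seed = 1)
#' table(d$is_filler)  # 42 main, 12 filler
#' @export
generate_design <- function(experiment, seed = 1L) {
  if (!experiment %in% c(1L, 2L)) stop("experiment must be 1 or 2")
  set.seed(as.integer(seed))

  pcts <- if (experiment == 1) TRUE_PCT_EXP1 else TRUE_PCT_EXP2
  reps <- if (experiment == 1) 1L else 2L
  n_filler <- if (experiment == 1) 12L else 15L

  main <- expand.grid(
    condition = c("uncertain", "certain"),
    peer_confidence = 1:3,
    true_pct = pcts,
    rep = seq_len(reps),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  main$rep <- NULL
  main$is_filler <- FALSE

  filler <- data.frame(
    condition = rep(c("uncertain", "certain"), length.out = n_filler),
    peer_confidence = rep(1:3, length.out = n_filler),
    true_pct = sample(0:100, n_filler, replace = TRUE),
    is_filler = TRUE,
    stringsAsFactors = FALSE)

  trials <- rbind(main, filler)
  trials$n_shown <- ifelse(trials$condition == "uncertain", 5L, 45L)

  # runs balanced on condition x filler status: shuffle within each stratum,
  # then deal trials round-robin over the 3 runs
  trials$run <- NA_integer_
  for (strat in split(seq_len(nrow(trials)),
                      list(trials$condition, trials$is_filler))) {
    strat <- sample(strat)
    trials$run[strat] <- rep(1:3, length.out = length(strat))
  }
  trials <- trials[order(trials$run, sample.int(nrow(trials))), ]
  trials$trial_index <- seq_len(nrow(trials))
  rownames(trials) <- NULL
  trials <- trials[, c("trial_index", "run", "condition", "n_shown",
                       "peer_confidence", "true_pct", "is_filler")]
  attr(trials, "experiment") <- as.integer(experiment)
  class(trials) <- c("socbayes_design", "data.frame")
  trials
}

#' Simulate the mushroom fields and the first estimate
#'
#' The mushrooms encountered in the fields are a noisy sample of the
#' forest: the blue count is a single binomial draw with `n_shown` trials
#' and success probability `true_pct / 100`. The first estimate faithfully
#' reports the seen proportion on the integer percentage grid:
#' `e1 = round(100 * blue_count / n_shown)`.
#'
#' @param true_pct True percentage(s) of blue mushrooms (0-100).
#' @param n_shown Number(s) of mushrooms shown (>= 1).
#' @param seed Optional integer seed; if `NULL` the current RNG state is
#'   used (so callers can manage seeding themselves).
#' @return A data frame with columns `blue_count` and `e1`.
#' @export
sample_fields <- function(true_pct, n_shown, seed = NULL) {
  stopifnot(all(true_pct >= 0 & true_pct <= 100), all(n_shown >= 1))
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- max(length(true_pct), length(n_shown))
  blue <- stats::rbinom(n, size = n_shown, prob = true_pct / 100)
  data.frame(blue_count = blue,
             e1 = as.integer(round(100 * blue / n_shown)))
}

#' Sample a peer estimate for one trial
#'
#' On main trials the peer's estimate lies 15 to 18 percentage points from
#' the first estimate and, whenever a value in 0..100 exists in that
#' direction, lies toward the true percentage; otherwise the opposite
#' direction is used. On filler trials the peer is either very close
#' (fewer than 3 points) or very far (more than 40 points) from the first
#' estimate, direction random within bounds.
#'
#' @param e1 First estimate (integer percent, 0-100).
#' @param true_pct True percentage of blue mushrooms.
#' @param is_filler Logical; filler trial?
#' @param seed Optional integer seed (see [sample_fields()]).
#' @return Integer peer estimate in 0..100. Vectorised over trials.
#' @examples
#' set.seed(1)
#' sample_peer(50, 75, FALSE)  # in 65..68, toward the truth
#' @export
sample_peer <- function(e1, true_pct, is_filler, seed = NULL) {
  stopifnot(all(e1 >= 0 & e1 <= 100))
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- max(length(e1), length(true_pct), length(is_filler))
  e1 <- rep_len(as.integer(round(e1)), n)
  true_pct <- rep_len(true_pct, n)
  is_filler <- rep_len(is_filler, n)
  vapply(seq_len(n), function(i) {
    if (is_filler[i]) sample_peer_filler(e1[i]) else
      sample_peer_main(e1[i], true_pct[i])
  }, integer(1))
}

sample_peer_main <- function(e1, true_pct) {
  dir <- sign(true_pct - e1)
  if (dir == 0) dir <- sample(c(-1L, 1L), 1L)
  for (d in list(dir, -dir)) {
    cand <- e1 + d * 15:18
    cand <- cand[cand >= 0 & cand <= 100]
    if (length(cand)) return(as.integer(resample(cand)))
  }
  stop("no admissible peer estimate for e1 = ", e1)  # unreachable for 0..100
}

sample_peer_filler <- function(e1) {
  near <- e1 + c(-2L, -1L, 1L, 2L)
  far <- c(0:max(0L, e1 - 41L), min(100L, e1 + 41L):100L)
  far <- far[abs(far - e1) > 40L]
  near <- near[near >= 0L & near <= 100L]
  pool <- if (stats::runif(1) < 0.5 && length(near)) near else far
  if (!length(pool)) pool <- near
  as.integer(resample(pool))
}

# sample() treats a length-1 numeric as 1:x; this never does
resample <- function(x) x[sample.int(length(x), 1L)]
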