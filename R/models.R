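# Beta-count observer models of social information use.
#
# An agent sees N mushrooms, reports a first estimate E1 of the percentage of
# blue mushrooms, views a peer's estimate P with a confidence rating, and
# reports a revised estimate E2.  Beliefs are beta distributions encoded as
# pseudo-counts (observations plus a unit prior of one blue and one red
# mushroom).  The model family varies three structural switches:
#   * alpha_mode  - how the objective count N maps onto a perceived count
#   * theta_mode  - how many observations the peer is credited with
#   * stay_mode   - a non-Bayesian mixture mass on repeating E1
# Responses live on the integer percentage grid 0..100; the posterior beta
# density is evaluated on that grid and renormalised so that, together with
# the stay mass, each trial's response distribution is a proper pmf.

MODEL_NAMES <- c("M0", "M1a", "M1b", "M2a", "M2b", "M2c",
                 "M3a", "M3b", "M3c", "M3d")

.ALPHA_BOUNDS <- c(0.1, 100)
.THETA_BOUNDS <- c(0.1, 1000)
.THETA_LIN_BOUNDS <- c(0.1, 500)
.BETA_BOUNDS <- c(0.01, 0.99)

RESPONSE_GRID <- seq(0, 1, by = 0.01)

#' Names of the registered observer models
#'
#' @return Character vector of the ten model names, ordered by increasing
#'   structural complexity.
#' @export
model_names <- function() MODEL_NAMES

#' Retrieve the specification of an observer model
#'
#' Each model is defined by three structural switches and the box bounds of
#' its free parameters:
#'
#' * `alpha_mode`: `"none"` (perceived count equals the shown count),
#'   `"single"` (one multiplicative distortion `alpha`), or `"dual"`
#'   (separate `alpha_uncertain` / `alpha_certain` per condition).
#' * `theta_mode`: `"fixed25"` (peer credited with 25 observations),
#'   `"single"` (`theta`), `"linear"`
#'   (`theta_ic + theta_slope * (confidence - 1)`), or `"per_level"`
#'   (one `theta` per confidence level).
#' * `stay_mode`: `"none"`, `"constant"` (`beta`), `"dual_condition"`
#'   (`beta_uncertain` / `beta_certain`), `"inverse_conf"`
#'   (`beta / confidence`), or `"power_conf"` (`beta ^ confidence`).
#'
#' @param name One of `model_names()`.
#' @return An object of class `socbayes_model`: a list with elements `name`,
#'   `alpha_mode`, `theta_mode`, `stay_mode`, `par_names` and `bounds`
#'   (named list of `c(lower, upper)`).
#' @examples
#' spec <- model_spec("M3d")
#' spec$par_names
#' @export
model_spec <- function(name) {
  name <- match.arg(name, MODEL_NAMES)
  alpha_mode <- switch(name, M0 = "none", M1a = "single", "dual")
  theta_mode <- switch(name,
    M0 = , M1a = , M1b = "fixed25",
    M2a = "single",
    M2c = "per_level",
    "linear")
  stay_mode <- switch(name,
    M3a = "constant", M3b = "dual_condition",
    M3c = "inverse_conf", M3d = "power_conf",
    "none")

  bounds <- list()
  if (alpha_mode == "single") bounds$alpha <- .ALPHA_BOUNDS
  if (alpha_mode == "dual") {
    bounds$alpha_uncertain <- .ALPHA_BOUNDS
    bounds$alpha_certain <- .ALPHA_BOUNDS
  }
  if (theta_mode == "single") bounds$theta <- .THETA_BOUNDS
  if (theta_mode == "linear") {
    bounds$theta_ic <- .THETA_LIN_BOUNDS
    bounds$theta_slope <- .THETA_LIN_BOUNDS
  }
  if (theta_mode == "per_level") {
    bounds$theta_low <- .THETA_BOUNDS
    bounds$theta_medium <- .THETA_BOUNDS
    bounds$theta_high <- .THETA_BOUNDS
  }
  if (stay_mode %in% c("constant", "inverse_conf", "power_conf"))
    bounds$beta <- .BETA_BOUNDS
  if (stay_mode == "dual_condition") {
    bounds$beta_uncertain <- .BETA_BOUNDS
    bounds$beta_certain <- .BETA_BOUNDS
  }

  structure(
    list(name = name, alpha_mode = alpha_mode, theta_mode = theta_mode,
         stay_mode = stay_mode, par_names = names(bounds), bounds = bounds),
    class = "socbayes_model")
}

as_model_spec <- function(model) {
  if (inherits(model, "socbayes_model")) model else model_spec(model)
}

#' @export
print.socbayes_model <- function(x, ...) {
  cat(sprintf("<socbayes_model %s: alpha=%s, theta=%s, stay=%s, k=%d>\n",
              x$name, x$alpha_mode, x$theta_mode, x$stay_mode,
              length(x$par_names)))
  invisible(x)
}

#' Validate a named parameter vector against a model's bounds
#'
#' @param spec A `socbayes_model` (or model name).
#' @param params Named numeric vector covering exactly the model's free
#'   parameters.
#' @return The parameter vector, invisibly, in the model's canonical order.
#' @export
check_params <- function(spec, params) {
  spec <- as_model_spec(spec)
  if (length(spec$par_names) == 0L) {
    if (length(params) > 0L)
      stop(spec$name, " has no free parameters")
    return(invisible(numeric(0)))
  }
  if (is.null(names(params)) || !setequal(names(params), spec$par_names))
    stop("params for ", spec$name, " must be named: ",
         paste(spec$par_names, collapse = ", "))
  params <- params[spec$par_names]
  for (p in spec$par_names) {
    b <- spec$bounds[[p]]
    if (!is.finite(params[[p]]) || params[[p]] < b[1] || params[[p]] > b[2])
      stop(sprintf("parameter %s = %g outside bounds [%g, %g]",
                   p, params[[p]], b[1], b[2]))
  }
  invisible(params)
}

#' Perceived number of own observations
#'
#' Maps the objective mushroom count onto the subjective count entering the
#' first-estimate belief: the identity for the base model, `n_shown * alpha`
#' for a single distortion parameter, or a condition-specific
#' `n_shown * alpha_condition` for the dual variant.
#'
#' @param spec A `socbayes_model` or model name.
#' @param params Named parameter vector.
#' @param condition Character vector, `"uncertain"` or `"certain"`.
#' @param n_shown Integer vector of shown mushroom counts.
#' @return Numeric vector of perceived counts.
#' @examples
#' perceived_n("M1b", c(alpha_uncertain = 28, alpha_certain = 4), "uncertain", 5)
#' @export
perceived_n <- function(spec, params, condition, n_shown) {
  spec <- as_model_spec(spec)
  switch(spec$alpha_mode,
    none = as.numeric(n_shown),
    single = n_shown * params[["alpha"]],
    dual = n_shown * ifelse(condition == "uncertain",
                            params[["alpha_uncertain"]],
                            params[["alpha_certain"]]))
}

#' Beta pseudo-counts of the first-estimate belief
#'
#' Adds the reported proportion of blue mushrooms, scaled by the perceived
#' count, to a unit prior of one blue and one red mushroom:
#' `blue = 1 + (e1/100) * n_perceived`, `red = 1 + (1 - e1/100) * n_perceived`.
#'
#' @param e1 First estimate in percent (0-100).
#' @param n_perceived Perceived observation count (>= 0).
#' @return List with numeric components `blue` and `red` (each >= 1).
#' @examples
#' e1_counts(20, 45)  # blue = 10, red = 37
#' @export
e1_counts <- function(e1, n_perceived) {
  stopifnot(all(e1 >= 0 & e1 <= 100), all(n_perceived >= 0))
  list(blue = 1 + e1 / 100 * n_perceived,
       red = 1 + (1 - e1 / 100) * n_perceived)
}

#' Number of observations credited to the peer
#'
#' @param spec A `socbayes_model` or model name.
#' @param params Named parameter vector.
#' @param peer_confidence Integer vector of confidence levels (1 = low,
#'   2 = medium, 3 = high).
#' @return Numeric vector: 25 for the fixed base model, `theta`,
#'   `theta_ic + theta_slope * (confidence - 1)`, or the level-specific
#'   `theta`, depending on the model's `theta_mode`.
#' @export
peer_n <- function(spec, params, peer_confidence) {
  spec <- as_model_spec(spec)
  stopifnot(all(peer_confidence %in% 1:3))
  switch(spec$theta_mode,
    fixed25 = rep(25, length(peer_confidence)),
    single = rep(params[["theta"]], length(peer_confidence)),
    linear = params[["theta_ic"]] +
      params[["theta_slope"]] * (peer_confidence - 1),
    per_level = c(params[["theta_low"]], params[["theta_medium"]],
                  params[["theta_high"]])[peer_confidence])
}

#' Posterior pseudo-counts after integrating the peer's estimate
#'
#' Strictly additive evidence accumulation: the peer's implied blue and red
#' counts are added to the first-estimate counts.
#'
#' @param e1c Belief counts as returned by [e1_counts()].
#' @param p Peer estimate in percent (0-100).
#' @param n_peer Observations credited to the peer (>= 0).
#' @return List with components `blue` and `red`.
#' @export
posterior_counts <- function(e1c, p, n_peer) {
  stopifnot(all(p >= 0 & p <= 100))
  list(blue = e1c$blue + p / 100 * n_peer,
       red = e1c$red + (1 - p / 100) * n_peer)
}

#' Discrete response distribution of a beta belief
#'
#' Evaluates the beta density with the given pseudo-counts at the 101
#' response options 0, 0.01, ..., 1 and renormalises the values to sum to
#' one, giving the likelihood of each integer percentage response.
#'
#' @param blue,red Beta shape parameters (pseudo-counts, each >= 1).
#'   Vectors of equal length produce one pmf per row.
#' @return A numeric matrix with one row per (blue, red) pair and 101
#'   columns; rows sum to 1.
#' @examples
#' p <- response_pmf(1, 1)   # uniform: every entry 1/101
#' stopifnot(abs(sum(p) - 1) < 1e-9)
#' @export
response_pmf <- function(blue, red) {
  stopifnot(length(blue) == length(red), all(blue >= 1), all(red >= 1))
  n <- length(blue)
  dens <- matrix(stats::dbeta(rep(RESPONSE_GRID, each = n), blue, red),
                 nrow = n, ncol = length(RESPONSE_GRID))
  if (any(!is.finite(dens)))
    stop("non-finite beta density; pseudo-counts must be >= 1")
  dens / rowSums(dens)
}

#' Stay-bias mixture weight
#'
#' The probability mass placed on repeating the first estimate regardless of
#' the peer's information: `beta` (constant), `beta_uncertain` /
#' `beta_certain` (per condition), `beta / confidence` (linear decrease), or
#' `beta ^ confidence` (exponential decrease).
#'
#' @param spec A `socbayes_model` or model name (must have a stay mode,
#'   except that models without one simply return 0).
#' @param params Named parameter vector.
#' @param peer_confidence Integer confidence level(s) in 1..3.
#' @param condition Condition label(s), used by the dual-condition variant.
#' @return Numeric vector of weights in \[0, 1).
#' @examples
#' stay_weight("M3d", c(alpha_uncertain = 1, alpha_certain = 1,
#'                      theta_ic = 1, theta_slope = 1, beta = 0.5), 3, "certain")
#' @export
stay_weight <- function(spec, params, peer_confidence, condition) {
  spec <- as_model_spec(spec)
  n <- max(length(peer_confidence), length(condition))
  switch(spec$stay_mode,
    none = rep(0, n),
    constant = rep(params[["beta"]], n),
    dual_condition = ifelse(condition == "uncertain",
                            params[["beta_uncertain"]],
                            params[["beta_certain"]]),
    inverse_conf = params[["beta"]] / peer_confidence,
    power_conf = params[["beta"]] ^ peer_confidence)
}

#' Full per-trial response distributions under a model
#'
#' For each trial, builds the posterior beta belief from `e1`, `p`, the
#' perceived own count and the peer count, converts it to a discrete pmf
#' over the 101 response options, and mixes in the stay mass at `e1`:
#' `P(E2 = k) = w * 1[k == e1] + (1 - w) * pmf[k]`.
#'
#' @param trials Data frame with columns `e1`, `p`, `condition`, `n_shown`,
#'   `peer_confidence` (integer percents for `e1`, `p`).
#' @param spec A `socbayes_model` or model name.
#' @param params Named parameter vector within bounds.
#' @return Numeric matrix, `nrow(trials)` x 101; each row a proper pmf.
#' @export
trial_response_probs <- function(trials, spec, params) {
  spec <- as_model_spec(spec)
  npv <- perceived_n(spec, params, trials$condition, trials$n_shown)
  e1c <- e1_counts(trials$e1, npv)
  npeer <- peer_n(spec, params, trials$peer_confidence)
  post <- posterior_counts(e1c, trials$p, npeer)
  q <- response_pmf(post$blue, post$red)
  w <- stay_weight(spec, params, trials$peer_confidence, trials$condition)
  probs <- q * (1 - w)
  idx <- cbind(seq_len(nrow(q)), as.integer(round(trials$e1)) + 1L)
  probs[idx] <- probs[idx] + w
  probs
}

#' Likelihood of a single observed second estimate
#'
#' With stay weight `w` and discrete posterior pmf `q`, a stay response
#' (`e2 == e1`) has probability `w + (1 - w) * q[e1]`; any other response has
#' probability `(1 - w) * q[e2]`.
#'
#' @param record One-row data frame with columns `e1`, `p`, `e2`,
#'   `condition`, `n_shown`, `peer_confidence`.
#' @param spec A `socbayes_model` or model name.
#' @param params Named parameter vector.
#' @return Probability of the observed `e2` (a number in (0, 1\]).
#' @export
trial_likelihood <- function(record, spec, params) {
  probs <- trial_response_probs(record, spec, params)
  probs[cbind(seq_len(nrow(record)), as.integer(round(record$e2)) + 1L)]
}

#' Negative log-likelihood of a participant's second estimates
#'
#' Sums `-log P(E2)` over the participant's evaluable trials: filler trials
#' are always excluded, and if the records carry an `included` column only
#' included trials enter. Probabilities are floored at `eps` so the result
#' is always finite.
#'
#' @param records Trial records for one participant.
#' @param spec A `socbayes_model` or model name.
#' @param params Named parameter vector.
#' @param eps Likelihood floor guarding against log(0); default 1e-12.
#' @return Scalar negative log-likelihood. The number of floored trials is
#'   attached as attribute `"n_floored"`.
#' @export
participant_nll <- function(records, spec, params, eps = 1e-12) {
  records <- evaluable_records(records)
  if (nrow(records) == 0L) stop("no evaluable (included, non-filler) trials")
  lik <- trial_likelihood(records, spec, params)
  floored <- sum(lik < eps)
  nll <- -sum(log(pmax(lik, eps)))
  attr(nll, "n_floored") <- floored
  nll
}

evaluable_records <- function(records) {
  keep <- !records$is_filler
  if (!is.null(records$included)) keep <- keep & records$included
  if (!is.null(records$missed)) keep <- keep & !records$missed
  records[keep, , drop = FALSE]
}

# Precompiled negative log-likelihood for repeated evaluation during
# fitting: hoists all data-frame work out of the objective. The returned
# closure takes a parameter vector in the model's canonical order.
make_nll <- function(records, spec, eps = 1e-12) {
  spec <- as_model_spec(spec)
  rec <- evaluable_records(records)
  if (nrow(rec) == 0L) stop("no evaluable (included, non-filler) trials")
  n <- nrow(rec)
  unc <- rec$condition == "uncertain"
  n_shown <- rec$n_shown
  e1f <- rec$e1 / 100
  pf <- rec$p / 100
  conf <- rec$peer_confidence
  is_stay <- rec$e2 == rec$e1
  e2_idx <- cbind(seq_len(n), as.integer(rec$e2) + 1L)
  gx <- rep(RESPONSE_GRID, each = n)
  am <- spec$alpha_mode; tm <- spec$theta_mode; sm <- spec$stay_mode

  function(params) {
    npv <- switch(am,
      none = n_shown,
      single = n_shown * params[["alpha"]],
      dual = n_shown * ifelse(unc, params[["alpha_uncertain"]],
                              params[["alpha_certain"]]))
    npeer <- switch(tm,
      fixed25 = 25,
      single = params[["theta"]],
      linear = params[["theta_ic"]] + params[["theta_slope"]] * (conf - 1),
      per_level = c(params[["theta_low"]], params[["theta_medium"]],
                    params[["theta_high"]])[conf])
    a <- 1 + e1f * npv + pf * npeer
    b <- 1 + (1 - e1f) * npv + (1 - pf) * npeer
    dens <- matrix(stats::dbeta(gx, a, b), nrow = n)
    q <- dens[e2_idx] / rowSums(dens)
    w <- switch(sm,
      none = 0,
      constant = params[["beta"]],
      dual_condition = ifelse(unc, params[["beta_uncertain"]],
                              params[["beta_certain"]]),
      inverse_conf = params[["beta"]] / conf,
      power_conf = params[["beta"]] ^ conf)
    lik <- (1 - w) * q + w * is_stay
    -sum(log(pmax(lik, eps)))
  }
}
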