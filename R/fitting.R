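# Per-participant maximum-likelihood estimation and BIC model comparison.
#
# Two-stage strategy: a log-spaced grid over the parameter box selects the
# best starting points, which are then refined with bounded L-BFG-S-B on the
# log-parameter scale (all bounds are strictly positive, and the likelihood
# is much better conditioned in log space for the count-scaling parameters).

#' Fitting configuration
#'
#' @param grid_points Grid resolution per parameter (log-spaced within the
#'   bounds). The full lattice is capped at `grid_cap` evaluations by
#'   coarsening, i.e. reducing the per-parameter resolution for
#'   high-dimensional models.
#' @param n_starts Number of top grid points used as optimiser starts.
#' @param grid_cap Maximum number of grid evaluations.
#' @param maxit L-BFGS-B iteration cap.
#' @param factr L-BFGS-B convergence tolerance (see [stats::optim()]).
#' @param eps Likelihood floor passed to [participant_nll()].
#' @return List of class `socbayes_fit_control`.
#' @export
fit_control <- function(grid_points = 5L, n_starts = 3L, grid_cap = 10000L,
                        maxit = 200L, factr = 1e7, eps = 1e-12) {
  structure(list(grid_points = as.integer(grid_points),
                 n_starts = as.integer(n_starts),
                 grid_cap = as.integer(grid_cap),
                 maxit = as.integer(maxit), factr = factr, eps = eps),
            class = "socbayes_fit_control")
}

#' Grid-search initialisation for one participant
#'
#' Evaluates the participant's negative log-likelihood on a log-spaced
#' lattice within the model's bounds and returns the best points as
#' optimiser starts.
#'
#' @param records One participant's trial records.
#' @param spec A `socbayes_model` or model name.
#' @param control A [fit_control()] list.
#' @return List with `starts` (list of named parameter vectors, best first),
#'   `nll` (their objective values) and `n_evaluated`.
#' @export
grid_init <- function(records, spec, control = fit_control()) {
  spec <- as_model_spec(spec)
  k <- length(spec$par_names)
  if (k == 0L) return(list(starts = list(numeric(0)), nll = NA_real_,
                           n_evaluated = 0L))
  npts <- control$grid_points
  while (npts > 2L && npts^k > control$grid_cap) npts <- npts - 1L
  axes <- lapply(spec$par_names, function(p) {
    b <- spec$bounds[[p]]
    exp(seq(log(b[1]), log(b[2]), length.out = npts))
  })
  names(axes) <- spec$par_names
  lattice <- as.matrix(expand.grid(axes, KEEP.OUT.ATTRS = FALSE))
  nll_fun <- make_nll(records, spec, eps = control$eps)
  nll <- apply(lattice, 1L, nll_fun)
  ord <- order(nll)[seq_len(min(control$n_starts, nrow(lattice)))]
  list(starts = lapply(ord, function(i) lattice[i, ]),
       nll = nll[ord],
       n_evaluated = nrow(lattice))
}

#' Fit one model to one participant by maximum likelihood
#'
#' Runs bounded quasi-Newton (L-BFGS-B) refinement from each grid start on
#' the log-parameter scale and keeps the solution with the lowest negative
#' log-likelihood. Deterministic given the records and control settings.
#'
#' @param records One participant's trial records (filler and non-included
#'   trials are ignored; see [participant_nll()]).
#' @param spec A `socbayes_model` or model name.
#' @param control A [fit_control()] list.
#' @param participant Optional id stored in the result (taken from the
#'   records when absent).
#' @return List of class `socbayes_fit`: `participant`, `model`, `params`,
#'   `nll`, `k`, `n_trials`, `bic`, `converged`, `n_starts_used`.
#' @export
fit_participant <- function(records, spec, control = fit_control(),
                            participant = NULL) {
  spec <- as_model_spec(spec)
  if (is.null(participant))
    participant <- as.character(records$participant[1])
  n_trials <- nrow(evaluable_records(records))
  if (n_trials == 0L) stop("no evaluable trials for ", participant)
  k <- length(spec$par_names)

  if (k == 0L) {
    nll <- as.numeric(participant_nll(records, spec, numeric(0),
                                      eps = control$eps))
    return(new_fit(participant, spec, numeric(0), nll, n_trials,
                   converged = TRUE, n_starts_used = 0L))
  }

  init <- grid_init(records, spec, control)
  lower <- log(vapply(spec$bounds, `[`, numeric(1), 1L))
  upper <- log(vapply(spec$bounds, `[`, numeric(1), 2L))
  nll_fun <- make_nll(records, spec, eps = control$eps)
  obj <- function(logp) nll_fun(stats::setNames(exp(logp), spec$par_names))

  best <- NULL
  any_ok <- FALSE
  for (start in init$starts) {
    res <- tryCatch(
      stats::optim(log(start), obj, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = control$maxit,
                                  factr = control$factr)),
      error = function(e) NULL)
    if (is.null(res)) next
    any_ok <- TRUE
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) {
    # all optimiser runs failed: report the best grid point, unconverged
    return(new_fit(participant, spec, init$starts[[1]], init$nll[1],
                   n_trials, converged = FALSE,
                   n_starts_used = length(init$starts)))
  }
  params <- stats::setNames(exp(best$par), spec$par_names)
  # refinement never does worse than its grid start
  if (best$value > init$nll[1] + 1e-9) {
    params <- init$starts[[1]]
    best$value <- init$nll[1]
  }
  new_fit(participant, spec, params, best$value, n_trials,
          converged = any_ok && best$convergence == 0,
          n_starts_used = length(init$starts))
}

new_fit <- function(participant, spec, params, nll, n_trials, converged,
                    n_starts_used) {
  k <- length(spec$par_names)
  structure(list(participant = participant, model = spec$name,
                 params = params, nll = nll, k = k, n_trials = n_trials,
                 bic = bic(nll, k, n_trials), converged = converged,
                 n_starts_used = n_starts_used),
            class = "socbayes_fit")
}

#' @export
print.socbayes_fit <- function(x, ...) {
  cat(sprintf("<%s fit for %s: nll=%.2f, BIC=%.2f (k=%d, n=%d)%s>\n",
              x$model, x$participant, x$nll, x$bic, x$k, x$n_trials,
              if (x$converged) "" else " [not converged]"))
  if (x$k > 0) print(round(x$params, 4))
  invisible(x)
}

#' Bayesian Information Criterion
#'
#' `BIC = k * ln(n) + 2 * nll`, where `k` is the number of free parameters
#' and `n` the number of trials entering the likelihood. Lower is better.
#'
#' @param nll Negative log-likelihood at the optimum.
#' @param k Number of free parameters.
#' @param n Number of observations.
#' @return Numeric BIC value.
#' @examples
#' bic(100, 2, 60)  # 2*log(60) + 200
#' @export
bic <- function(nll, k, n) k * log(n) + 2 * nll

#' Fit several models to every participant of a cohort
#'
#' @param records Cohort trial records (column `participant` groups trials).
#' @param models Character vector of model names (default: all ten).
#' @param control A [fit_control()] list.
#' @return Data frame with one row per participant x model: `participant`,
#'   `model`, `k`, `n_trials`, `nll`, `bic`, `converged`, and a list-column
#'   `params`.
#' @export
fit_cohort <- function(records, models = model_names(),
                       control = fit_control()) {
  ids <- unique(records$participant)
  rows <- list()
  for (m in models) {
    spec <- model_spec(m)
    for (id in ids) {
      f <- fit_participant(records[records$participant == id, ], spec,
                           control = control, participant = id)
      rows[[length(rows) + 1L]] <- data.frame(
        participant = id, model = m, k = f$k, n_trials = f$n_trials,
        nll = f$nll, bic = f$bic, converged = f$converged,
        stringsAsFactors = FALSE)
      rows[[length(rows)]]$params <- list(f$params)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cross-model BIC comparison table
#'
#' Sums per-participant BICs per model and reports each model's difference
#' from the best (lowest-BIC) model.
#'
#' @param fits A fit table from [fit_cohort()] covering every participant
#'   under every model.
#' @return Data frame of class `socbayes_comparison` (`model`, `k`,
#'   `total_bic`, `delta_bic`, `winner`), sorted by the canonical model
#'   order, with the winning model name in attribute `"winner"`.
#' @export
compare_models <- function(fits) {
  tab <- table(fits$participant, fits$model)
  if (any(tab != 1L))
    stop("every participant must be fitted exactly once under every model")
  total <- tapply(fits$bic, fits$model, sum)
  k <- tapply(fits$k, fits$model, max)
  models <- intersect(model_names(), names(total))
  out <- data.frame(model = models,
                    k = as.integer(k[models]),
                    total_bic = as.numeric(total[models]),
                    stringsAsFactors = FALSE)
  out$delta_bic <- out$total_bic - min(out$total_bic)
  out$winner <- out$delta_bic == 0
  attr(out, "winner") <- out$model[which.min(out$total_bic)]
  class(out) <- c("socbayes_comparison", "data.frame")
  out
}

#' Replay the conditional model-building sequence
#'
#' Walks the model sequence in order of increasing complexity, accepting a
#' model only if its total BIC improves on the last accepted model; rejected
#' models are not used as a basis for further development.
#'
#' @param comparison A [compare_models()] table.
#' @return Data frame with columns `model`, `total_bic`, `accepted`, and the
#'   accepted path in attribute `"path"`.
#' @export
model_building_path <- function(comparison) {
  comparison <- comparison[order(match(comparison$model, model_names())), ]
  accepted <- logical(nrow(comparison))
  best <- Inf
  for (i in seq_len(nrow(comparison))) {
    if (comparison$total_bic[i] < best) {
      accepted[i] <- TRUE
      best <- comparison$total_bic[i]
    }
  }
  out <- data.frame(model = comparison$model,
                    total_bic = comparison$total_bic,
                    accepted = accepted, stringsAsFactors = FALSE)
  attr(out, "path") <- out$model[accepted]
  out
}
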