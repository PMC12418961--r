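# Model recovery and parameter recovery diagnostics.

#' Model-recovery confusion matrix
#'
#' For each generator model, simulates a cohort with parameters drawn
#' uniformly from the simulation ranges, fits every candidate model to the
#' cohort, and assigns the cohort's winner by total BIC. The result is a
#' generator x fitter matrix whose rows are indicator distributions over
#' the winning model (rows sum to 1).
#'
#' @param models Character vector of models used both as generators and
#'   fitters; defaults to the nine models with free parameters (all but the
#'   base model).
#' @param n_per_model Simulated participants per generator cohort.
#' @param ranges Optional named list of per-model parameter ranges (each as
#'   in [sample_parameters()]); defaults per model to
#'   [default_sim_ranges()].
#' @param experiment Task design used for simulation (1 or 2).
#' @param seed Integer seed.
#' @param control A [fit_control()] list; recovery studies typically use a
#'   coarser grid than single-cohort fits.
#' @return List of class `socbayes_confusion`: `confusion` (winner
#'   indicator matrix), `total_bic` (generator x fitter total-BIC matrix),
#'   `n_per_model`, `n_fit_procedures` (generators x fitters), and
#'   `failures` (data frame of any unconverged fits).
#' @export
model_recovery <- function(models = setdiff(model_names(), "M0"),
                           n_per_model = 10L, ranges = NULL,
                           experiment = 2L, seed = 1L,
                           control = fit_control(grid_points = 3L,
                                                 n_starts = 1L)) {
  stopifnot(n_per_model >= 1L)
  set.seed(as.integer(seed))
  gen_seeds <- sample.int(.Machine$integer.max - 1L, 2L * length(models))
  m <- length(models)
  confusion <- matrix(0, m, m, dimnames = list(generator = models,
                                               fitter = models))
  totals <- confusion
  failures <- list()
  n_procedures <- 0L

  for (gi in seq_along(models)) {
    g <- models[gi]
    pars <- sample_parameters(g, n_per_model,
                              ranges = ranges[[g]],
                              seed = gen_seeds[2 * gi - 1])
    cohort <- simulate_cohort(n_per_model, g, pars, experiment = experiment,
                              seed = gen_seeds[2 * gi])
    cohort <- apply_trial_filters(cohort)
    fits <- fit_cohort(cohort, models = models, control = control)
    n_procedures <- n_procedures + m
    if (any(!fits$converged))
      failures[[g]] <- fits[!fits$converged,
                            c("participant", "model", "nll", "bic")]
    cmp <- compare_models(fits)
    totals[g, cmp$model] <- cmp$total_bic
    confusion[g, attr(cmp, "winner")] <- 1
  }

  structure(list(confusion = confusion, total_bic = totals,
                 n_per_model = as.integer(n_per_model),
                 n_fit_procedures = n_procedures,
                 failures = if (length(failures))
                   do.call(rbind, failures) else NULL),
            class = "socbayes_confusion")
}

#' @export
print.socbayes_confusion <- function(x, ...) {
  cat(sprintf("Model recovery: %d cohorts of %d participants, %d fitting procedures\n",
              nrow(x$confusion), x$n_per_model, x$n_fit_procedures))
  print(x$confusion)
  invisible(x)
}

#' Parameter-recovery correlations for one model
#'
#' Simulates participants with "true" parameters drawn uniformly from the
#' simulation ranges, refits the same model to each simulated participant,
#' and reports the Pearson correlation between true and fitted values per
#' parameter.
#'
#' @param spec A `socbayes_model` or model name.
#' @param n_sim Number of simulated participants (>= 3).
#' @param ranges Parameter ranges as in [sample_parameters()].
#' @param experiment Task design used for simulation (default 2: 60
#'   non-filler trials).
#' @param seed Integer seed.
#' @param control A [fit_control()] list.
#' @return List of class `socbayes_recovery`: `model`, `summary` (data
#'   frame per parameter: `r`, `p`, `n`; `r` is `NA` for a zero-variance
#'   true vector), `true` and `fitted` (n_sim x k data frames), and
#'   `min_r`.
#' @export
parameter_recovery <- function(spec, n_sim = 50L, ranges = NULL,
                               experiment = 2L, seed = 1L,
                               control = fit_control()) {
  spec <- as_model_spec(spec)
  stopifnot(n_sim >= 3L)
  set.seed(as.integer(seed))
  seeds <- sample.int(.Machine$integer.max - 1L, 2L)
  pars <- sample_parameters(spec, n_sim, ranges = ranges, seed = seeds[1])
  cohort <- simulate_cohort(n_sim, spec, pars, experiment = experiment,
                            seed = seeds[2])
  cohort <- apply_trial_filters(cohort)

  ids <- unique(cohort$participant)
  fitted <- lapply(ids, function(id)
    fit_participant(cohort[cohort$participant == id, ], spec,
                    control = control, participant = id)$params)
  true_df <- as.data.frame(do.call(rbind, pars))
  fit_df <- as.data.frame(do.call(rbind, fitted))

  summ <- do.call(rbind, lapply(spec$par_names, function(p) {
    x <- true_df[[p]]; y <- fit_df[[p]]
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      return(data.frame(parameter = p, r = NA_real_, p_value = NA_real_,
                        n = length(x), stringsAsFactors = FALSE))
    ct <- stats::cor.test(x, y)
    data.frame(parameter = p, r = unname(ct$estimate),
               p_value = ct$p.value, n = length(x), stringsAsFactors = FALSE)
  }))

  structure(list(model = spec$name, summary = summ,
                 true = true_df, fitted = fit_df,
                 min_r = suppressWarnings(min(summ$r, na.rm = TRUE))),
            class = "socbayes_recovery")
}

#' @export
print.socbayes_recovery <- function(x, ...) {
  cat(sprintf("Parameter recovery for %s (n = %d):\n", x$model,
              x$summary$n[1]))
  print(x$summary, digits = 3)
  invisible(x)
}
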