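# End-to-end orchestration of the canonical analysis pipeline:
# simulate -> filter -> regress-behavior -> fit -> compare -> recover ->
# regressors, with a single seeded configuration and a run manifest.

#' Default pipeline configuration
#'
#' All tunables silent in the task description live here with documented
#' defaults: the generating model and its simulation ranges, the cohort
#' size, the model list, grid and optimiser settings, and which stages run.
#' A configuration fully determines the pipeline output.
#'
#' @param seed Master seed; every stage derives its randomness from it.
#' @param experiment Task design (1 or 2).
#' @param n_participants Simulated cohort size.
#' @param generating_model Model that simulates the cohort.
#' @param models Models fitted and compared.
#' @param stages Ordered subset of `simulate`, `filter`, `regress_behavior`,
#'   `fit`, `compare`, `recover`, `regressors`.
#' @param fit Settings passed to [fit_control()].
#' @param recover Settings for the recovery stage (`n_per_model`,
#'   `grid_points`, `n_starts`).
#' @param out_dir Output directory, or `NULL` to keep results in memory.
#' @param overwrite Allow writing into an existing non-empty `out_dir`.
#' @return Nested list of class `socbayes_config`.
#' @export
default_config <- function(seed = 1L, experiment = 2L, n_participants = 20L,
                           generating_model = "M3d",
                           models = model_names(),
                           stages = c("simulate", "filter",
                                      "regress_behavior", "fit", "compare",
                                      "regressors"),
                           fit = list(), recover = list(n_per_model = 5L),
                           out_dir = NULL, overwrite = FALSE) {
  structure(list(seed = as.integer(seed), experiment = as.integer(experiment),
                 n_participants = as.integer(n_participants),
                 generating_model = generating_model, models = models,
                 stages = stages, fit = fit, recover = recover,
                 out_dir = out_dir, overwrite = overwrite),
            class = c("socbayes_config", "list"))
}

#' Read a pipeline configuration from YAML
#'
#' Fields present in the file override the [default_config()] values.
#'
#' @param path YAML file path.
#' @return A `socbayes_config` list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  for (nm in names(user)) cfg[[nm]] <- user[[nm]]
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' Run the canonical analysis pipeline
#'
#' Executes the configured stages in order on a simulated cohort and
#' returns a manifest recording seeds, per-stage content hashes, exclusion
#' counts and the winning model. Later stages consume earlier ones
#' (`compare` requires `fit`, `regress_behavior` and `fit` require
#' `filter`); a missing prerequisite is an error. When `out_dir` is set,
#' stage outputs are written there (trial table, exclusion report,
#' regression JSON, comparison table, event files) and the directory is
#' never overwritten unless `overwrite = TRUE`.
#'
#' @param config A [default_config()] list.
#' @return Invisibly, a list with `manifest` and the in-memory stage
#'   `results`.
#' @export
run_pipeline <- function(config = default_config()) {
  stages <- match.arg(config$stages,
                      c("simulate", "filter", "regress_behavior", "fit",
                        "compare", "recover", "regressors"),
                      several.ok = TRUE)
  out_dir <- config$out_dir
  if (!is.null(out_dir)) {
    if (dir.exists(out_dir) && length(list.files(out_dir)) &&
        !isTRUE(config$overwrite))
      stop("output directory ", out_dir,
           " is not empty; set overwrite = TRUE to reuse it")
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  }

  set.seed(config$seed)
  stage_seeds <- stats::setNames(
    sample.int(.Machine$integer.max - 1L, 7L),
    c("simulate", "filter", "regress_behavior", "fit", "compare",
      "recover", "regressors"))

  res <- list()
  manifest <- list(package_version = as.character(utils::packageVersion("socbayes")),
                   seed = config$seed, stage_seeds = as.list(stage_seeds),
                   stages = stages, hashes = list())

  need <- function(el, dep, stage) {
    if (is.null(res[[el]]))
      stop("stage '", stage, "' requires stage '", dep, "' to run first")
  }

  for (stage in stages) {
    switch(stage,
      simulate = {
        pars <- sample_parameters(config$generating_model,
                                  config$n_participants,
                                  seed = stage_seeds[["simulate"]])
        res$cohort <- simulate_cohort(config$n_participants,
                                      config$generating_model, pars,
                                      experiment = config$experiment,
                                      seed = stage_seeds[["simulate"]])
        if (!is.null(out_dir))
          write_trials(res$cohort, file.path(out_dir, "trials.tsv"))
      },
      filter = {
        need("cohort", "simulate", "filter")
        filtered <- apply_trial_filters(res$cohort)
        pf <- apply_participant_filters(filtered)
        res$records <- pf$records
        res$participant_log <- pf$log
        manifest$exclusion_counts <-
          as.list(table(res$records$exclusion_reason))
        manifest$n_participants_retained <- sum(pf$log$retained)
        if (!is.null(out_dir))
          write_exclusion_report(res$records,
                                 file.path(out_dir, "exclusions.tsv"))
      },
      regress_behavior = {
        need("records", "filter", "regress_behavior")
        res$regression <- fit_condition_regression(res$records)
        if (!is.null(out_dir))
          write_regression_json(res$regression,
                                file.path(out_dir, "regression.json"))
      },
      fit = {
        need("records", "filter", "fit")
        res$fits <- fit_cohort(res$records, models = config$models,
                               control = do.call(fit_control, config$fit))
      },
      compare = {
        need("fits", "fit", "compare")
        res$comparison <- compare_models(res$fits)
        manifest$winner <- attr(res$comparison, "winner")
        if (!is.null(out_dir)) {
          utils::write.table(res$comparison,
                             file.path(out_dir, "comparison.tsv"),
                             sep = "\t", quote = FALSE, row.names = FALSE)
          jsonlite::write_json(as.data.frame(res$comparison),
                               file.path(out_dir, "comparison.json"),
                               auto_unbox = TRUE, digits = NA)
        }
      },
      recover = {
        rc <- config$recover
        res$recovery <- model_recovery(
          n_per_model = rc$n_per_model %||% 5L,
          experiment = config$experiment,
          seed = stage_seeds[["recover"]],
          control = fit_control(grid_points = rc$grid_points %||% 3L,
                                n_starts = rc$n_starts %||% 1L))
      },
      regressors = {
        need("records", "filter", "regressors")
        need("fits", "fit", "regressors")
        reg_model <- config$regressor_model %||% "M3d"
        fits <- res$fits[res$fits$model == reg_model, ]
        if (nrow(fits) == 0L)
          stop("no fits available for regressor model ", reg_model)
        res$regressor_sets <- lapply(seq_len(nrow(fits)), function(i) {
          rec <- res$records[res$records$participant == fits$participant[i], ]
          build_regressors(rec, fits$params[[i]])
        })
        names(res$regressor_sets) <- fits$participant
        if (!is.null(out_dir)) {
          ev_dir <- file.path(out_dir, "events")
          for (rs in res$regressor_sets)
            for (w in c("certainty", "peer_confidence_reg", "kl"))
              export_events(rs, w, dir = ev_dir)
          jsonlite::write_json(lapply(fits$params, as.list),
                               file.path(out_dir, "fitted_params.json"),
                               auto_unbox = TRUE, digits = NA)
        }
      })
    manifest$hashes[[stage]] <- rlang::hash(hashable_results(res))
  }

  if (!is.null(out_dir))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(manifest = manifest, results = res))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# fitted mixed-model objects carry environments that do not serialise
# reproducibly; hash only their stable summaries
hashable_results <- function(res) {
  if (!is.null(res$regression))
    res$regression <- unclass(res$regression)[
      c("fixed", "ranef_variances", "n_participants", "n_trials",
        "formula", "structure_used", "fallbacks")]
  res
}
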