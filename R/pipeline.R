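#' Pipeline configuration
#'
#' @param out_dir Output directory for stage tables and reports.
#' @param seed Single seed driving all pipeline randomness.
#' @param spec A [cohort_spec()] for the simulate stage (its own seed is
#'   overridden by `seed`).
#' @param stages Character subset of `c("simulate", "motor", "patterns",
#'   "classify")` to run; stages always execute in dependency order.
#' @param q FDR level used throughout (default 0.05).
#' @param classify_repetitions Repetitions for the nested LOOCV.
#' @param elbow_repetitions Repetitions for the elbow estimate.
#' @param use_covariates Adjust tests/correlations for age and gender
#'   (default TRUE).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, spec = NULL,
                            stages = c("simulate", "motor", "patterns",
                                       "classify"),
                            q = 0.05, classify_repetitions = 100,
                            elbow_repetitions = 100,
                            use_covariates = TRUE) {
  stopifnot(q > 0, q < 1)
  stages <- match.arg(stages, several.ok = TRUE)
  if (is.null(spec)) spec <- cohort_spec(seed = seed)
  spec$seed <- as.integer(seed)
  structure(list(out_dir = out_dir, seed = as.integer(seed), spec = spec,
                 stages = stages, q = q,
                 classify_repetitions = classify_repetitions,
                 elbow_repetitions = elbow_repetitions,
                 use_covariates = use_covariates),
            class = "pipeline_config")
}

#' Run the analysis pipeline
#'
#' Executes the configured stages in dependency order — simulate (generate
#' and write a synthetic cohort), motor (subnetwork ON/OFF tests, seed
#' post-hocs in significant bands, OFF-state UPDRS correlation), patterns
#' (per-band ON-state PCA, elbow selection, cognition correlations) and
#' classify (nested LOOCV) — writing CSV tables and JSON reports under
#' `out_dir` together with a run record (config hash, seed, package version,
#' per-stage wall time, collected warnings). Identical config and seed give
#' identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param cohort Optional pre-built cohort; when supplied the simulate stage
#'   only writes it.
#' @return List with the stage results and the `run_record`, invisibly
#'   written to `out_dir/run_record.json`.
#' @export
run_pipeline <- function(config, cohort = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  warnings_log <- character(0)
  note <- function(w) {
    warnings_log <<- c(warnings_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  }
  timings <- list()
  results <- list()
  timed <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- withCallingHandlers(expr, warning = note)
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    out
  }

  if (is.null(cohort)) {
    cohort <- timed("simulate", generate_fc_cohort(config$spec))
  }
  if ("simulate" %in% config$stages) {
    timed("write_cohort",
          write_cohort(cohort, file.path(config$out_dir, "cohort")))
  }
  covs <- if (config$use_covariates) covariate_matrix(cohort$metadata)
    else NULL

  if ("motor" %in% config$stages) {
    results$motor <- timed("motor", {
      test <- on_off_subnetwork_test(cohort, covs, config$q)
      posthoc <- lapply(test$table$band[test$table$significant],
                        function(bn) {
                          seed_posthoc_tests(cohort, bn, covs, config$q)
                        })
      names(posthoc) <- test$table$band[test$table$significant]
      motor_band <- cohort$spec$motor_band %||% "hgamma"
      ev <- test$eigenvariates[[motor_band]]
      corr <- correlate_off_with_updrs(ev$scores_off,
                                       cohort$metadata$updrs_diff, covs)
      utils::write.csv(test$table,
                       file.path(config$out_dir, "motor_band_tests.csv"),
                       row.names = FALSE)
      utils::write.csv(ev$loading_matrix,
                       file.path(config$out_dir, "motor_loadings.csv"))
      list(band_tests = test, posthoc = posthoc, off_updrs = corr,
           eigenvariate = ev)
    })
  }

  if ("patterns" %in% config$stages) {
    results$patterns <- timed("patterns", {
      per_band <- lapply(names(cohort$spec$bands), function(bn) {
        band_pattern_analysis(cohort, bn, covs,
                              repetitions = config$elbow_repetitions,
                              seed = config$seed, q = config$q)
      })
      names(per_band) <- names(cohort$spec$bands)
      scree <- do.call(rbind, lapply(names(per_band), function(bn) {
        ve <- per_band[[bn]]$pca$variance_explained
        data.frame(band = bn, component = seq_along(ve),
                   variance_explained = ve)
      }))
      utils::write.csv(scree, file.path(config$out_dir, "scree.csv"),
                       row.names = FALSE)
      grid <- do.call(rbind, lapply(names(per_band), function(bn) {
        cbind(band = bn, per_band[[bn]]$correlations)
      }))
      utils::write.csv(grid,
                       file.path(config$out_dir, "cognition_correlations.csv"),
                       row.names = FALSE)
      per_band
    })
  }

  if ("classify" %in% config$stages) {
    results$classify <- timed("classify", {
      rep <- nested_loocv(cohort, repetitions = config$classify_repetitions,
                          seed = config$seed)
      utils::write.csv(rep$final_profile[setdiff(names(rep$final_profile),
                                                 "col")],
                       file.path(config$out_dir, "final_profile.csv"),
                       row.names = FALSE)
      jsonlite::write_json(
        list(ppv = rep$ppv, npv = rep$npv, sensitivity = rep$sensitivity,
             specificity = rep$specificity,
             final_threshold = rep$final_threshold,
             chosen_threshold = rep$chosen_threshold,
             n_unclassifiable = rep$n_unclassifiable),
        file.path(config$out_dir, "classification_report.json"),
        auto_unbox = TRUE, digits = NA)
      rep
    })
  }

  cfg_json <- jsonlite::toJSON(config[setdiff(names(config), "spec")],
                               auto_unbox = TRUE, force = TRUE)
  cfg_file <- tempfile()
  writeLines(as.character(cfg_json), cfg_file)
  run_record <- list(
    config_hash = unname(tools::md5sum(cfg_file)),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("dbsconnect")),
    stage_seconds = timings,
    warnings = warnings_log)
  unlink(cfg_file)
  jsonlite::write_json(run_record, file.path(config$out_dir,
                                             "run_record.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(results, list(run_record = run_record, cohort = cohort)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
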