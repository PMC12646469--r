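# Configuration-driven pipeline: simulate/load -> fit -> evaluate ->
# compare -> explain, with a manifest recording every seed.

run_config_defaults <- function() {
  list(
    cohort_path = NULL,
    synthetic = list(n_patients = 200L, beta = list(), target_prevalence = 0.38),
    rdi_path = NULL, intakes_path = NULL,
    grid = list(stages = c("simple", "lr_hybrid", "abc_lr_hybrid"),
                bases = c("rf", "knn", "svm", "cart")),
    cv = list(k = 5L, resampling = "smote_within_fold", smote_neighbors = 5L),
    abc = list(n_sources = 15L, max_iterations = 30L, abandonment = 0.01),
    inner_cv = 3L, metric = "f1", l1_strength = 0.05,
    explain = list(n_perturbations = 1000L, max_features = 10L,
                   instances = 1L),
    seed = 1L, log_level = "info"
  )
}

# recursively check that every key in `cfg` exists in `defaults`
check_config_keys <- function(cfg, defaults, path = "") {
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown) > 0L) {
    stop("parse_run_config: unknown key(s): ",
         paste0(path, unknown, collapse = ", "), call. = FALSE)
  }
  for (k in names(cfg)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]])) &&
        is.list(cfg[[k]])) {
      check_config_keys(cfg[[k]], defaults[[k]], paste0(path, k, "."))
    }
  }
}

merge_config <- function(defaults, cfg) {
  for (k in names(cfg)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]])) &&
        is.list(cfg[[k]])) {
      defaults[[k]] <- merge_config(defaults[[k]], cfg[[k]])
    } else {
      defaults[[k]] <- cfg[[k]]
    }
  }
  defaults
}

#' Parse a run configuration
#'
#' Reads a YAML or JSON configuration, validates keys against the known
#' schema (unknown keys are an error, named with their path), fills
#' defaults (5-fold CV, 15 food sources, 30 iterations, the
#' abandonment-fraction rule), and enforces that exactly one of a cohort
#' path or a synthetic-cohort block drives the run.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file; `NULL` for defaults
#'   only.
#' @param overrides named list merged over the file's values.
#' @return list of class `run_config`, fully resolved.
#' @export
parse_run_config <- function(path = NULL, overrides = list()) {
  cfg <- list()
  if (!is.null(path)) {
    cfg <- if (grepl("\\.ya?ml$", path)) {
      yaml::read_yaml(path)
    } else {
      jsonlite::fromJSON(path, simplifyVector = TRUE)
    }
  }
  defaults <- run_config_defaults()
  check_config_keys(cfg, defaults)
  check_config_keys(overrides, defaults)
  out <- merge_config(merge_config(defaults, cfg), overrides)
  explicit_synthetic <- !is.null(cfg$synthetic) || !is.null(overrides$synthetic)
  if (!is.null(out$cohort_path) && explicit_synthetic) {
    stop("parse_run_config: set exactly one of cohort_path or synthetic",
         call. = FALSE)
  }
  structure(out, class = "run_config")
}

#' Run the full experiment described by a configuration
#'
#' Simulates (or loads) the cohort, runs the cross-validated comparison
#' over the model grid, explains one or more test instances with the best
#' model, and writes everything to `out_dir`: `comparison.csv`,
#' `fold_metrics.csv`, `calibration.csv` and `oof_predictions.csv` for the
#' best model, `explanation_*.json`, and `manifest.json` recording the
#' fully resolved configuration and every derived seed. Deterministic for
#' a fixed global seed.
#'
#' @param config a [run_config][parse_run_config()].
#' @param out_dir output directory (created if needed).
#' @param quiet suppress progress messages.
#' @return the [comparison_table()] invisibly, with attribute `out_dir`.
#' @export
run_experiment <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  seeds <- list(cohort = derive_seed(seed, "cohort"),
                cv = derive_seed(seed, "cv"),
                model = derive_seed(seed, "model"),
                explain = derive_seed(seed, "explain"))

  cohort <- if (!is.null(config$cohort_path)) {
    read_cohort(config$cohort_path, quiet = quiet)
  } else {
    beta <- unlist(config$synthetic$beta)
    generate_cohort(synthetic_config(
      n = config$synthetic$n_patients, seed = seeds$cohort,
      beta = if (length(beta)) beta else numeric(0),
      target_prevalence = config$synthetic$target_prevalence))
  }

  abc <- abc_config(config$abc$n_sources, config$abc$max_iterations,
                    config$abc$abandonment, seed = seeds$model)
  grid <- model_grid(bases = config$grid$bases, stages = config$grid$stages,
                     abc = abc, inner_cv = config$inner_cv,
                     metric = config$metric,
                     l1_strength = config$l1_strength, seed = seeds$model)
  cv <- cv_config(k = config$cv$k, resampling = config$cv$resampling,
                  smote_neighbors = config$cv$smote_neighbors,
                  seed = seeds$cv)
  comparison <- comparison_table(cohort, grid, cv, quiet = quiet)
  utils::write.csv(as.data.frame(comparison)[,
    c("no", "stage", "model", "accuracy", "f_score", "recall", "precision",
      "model_type", "best", "failed")],
    file.path(out_dir, "comparison.csv"), row.names = FALSE)

  reports <- attr(comparison, "reports")
  folds_out <- do.call(rbind, lapply(names(reports), function(nm) {
    cbind(model = nm, reports[[nm]]$fold_metrics)
  }))
  utils::write.csv(folds_out, file.path(out_dir, "fold_metrics.csv"),
                   row.names = FALSE)

  best_label <- comparison$model[comparison$best][1]
  if (!is.na(best_label) && best_label %in% names(reports)) {
    best_rep <- reports[[best_label]]
    utils::write.csv(best_rep$probability$calibration,
                     file.path(out_dir, "calibration.csv"), row.names = FALSE)
    utils::write.csv(best_rep$predictions,
                     file.path(out_dir, "oof_predictions.csv"),
                     row.names = FALSE)
    # explanations from the best spec refitted on the full cohort
    fitted <- with_seed(seeds$model, {
      sp <- grid[[best_label]]; sp$seed <- seeds$model
      fit_model(build_model(sp), cohort_matrix(cohort), cohort_outcome(cohort))
    })
    ec <- explain_config(n_perturbations = config$explain$n_perturbations,
                         max_features = config$explain$max_features,
                         seed = seeds$explain)
    n_inst <- min(config$explain$instances, nrow(cohort))
    for (i in seq_len(n_inst)) {
      ex <- explain_instance(fitted, cohort_matrix(cohort)[i, ], cohort, ec)
      explanation_to_json(ex, file.path(out_dir,
                                        sprintf("explanation_%03d.json", i)))
    }
  }

  manifest <- list(config = unclass(config), seeds = seeds,
                   n = nrow(cohort),
                   outcome_prevalence = mean(cohort_outcome(cohort)),
                   best_model = best_label,
                   package_version = as.character(utils::packageVersion("ivfabc")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  attr(comparison, "out_dir") <- out_dir
  invisible(comparison)
}
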