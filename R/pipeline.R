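#' End-to-end run configuration
#'
#' Every stochastic stage's seed is derived from the config so a run is a
#' pure function of it: the cohort uses `cohort$seed` and the
#' cross-validation stage uses `cv_seed`.
#'
#' @param cohort A [cohort_config()].
#' @param iqr_k IQR fence multiplier for cleaning.
#' @param iqr_scope Fence scope, see [build_feature_table()].
#' @param cv_k Cross-validation folds.
#' @param cv_seed Seed for fold assignment and boosters.
#' @param positive_class Event label for models and metrics.
#' @param group_by_subject Subject-grouped CV (see
#'   [run_feature_set_comparison()]).
#' @param n_estimators,learning_rate,max_depth Booster hyperparameters.
#' @return An object of class `tms_run_config`.
#' @export
run_config <- function(cohort = cohort_config(),
                       iqr_k = 1.5,
                       iqr_scope = "global",
                       cv_k = 10L,
                       cv_seed = 1L,
                       positive_class = "MDD",
                       group_by_subject = FALSE,
                       n_estimators = 250L,
                       learning_rate = 0.1,
                       max_depth = 8L) {
  stopifnot(inherits(cohort, "tms_cohort_config"))
  structure(
    list(cohort = cohort, iqr_k = iqr_k, iqr_scope = iqr_scope,
         cv_k = check_scalar_count(cv_k, "cv_k", min = 2L),
         cv_seed = check_scalar_count(cv_seed, "cv_seed", min = 0L),
         positive_class = positive_class,
         group_by_subject = isTRUE(group_by_subject),
         n_estimators = n_estimators, learning_rate = learning_rate,
         max_depth = max_depth),
    class = "tms_run_config"
  )
}

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Simulate (or load) a stimulation table, clean it, compute the
#' excitability metrics, fit the per-cell Gamma distributions, run the
#' principal-component mixed-effects logistic model, and run the
#' three-feature-set classifier comparison with attribution. All tables are
#' written as CSV and all reports as JSON under `output_dir`; a manifest
#' records the configuration and package version. Rerunning with the same
#' config reproduces every output byte-for-byte.
#'
#' @param config A [run_config()].
#' @param output_dir Writable output directory (created if absent).
#' @param stimulation Optional pre-existing stimulation table; when supplied
#'   the simulation stage is skipped (so real recordings in the same schema
#'   can be substituted for synthetic ones).
#' @return Invisibly, a list with all in-memory stage results:
#'   `stimulation`, `features`, `cleaning_report`, `distribution_report`,
#'   `pc_glmm`, `comparison`, `attribution`, `manifest`.
#' @export
run_pipeline <- function(config, output_dir, stimulation = NULL) {
  stopifnot(inherits(config, "tms_run_config"))
  if (!dir.exists(output_dir)) {
    ok <- dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop_param("cannot create output directory: ", output_dir)
  }
  probe <- file.path(output_dir, ".write_probe")
  ok <- tryCatch({ file.create(probe, showWarnings = FALSE) },
                 error = function(e) FALSE)
  if (!isTRUE(ok)) stop_param("output directory is not writable: ", output_dir)
  unlink(probe)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_param("pipeline stage '", name, "' failed: ", conditionMessage(e))
    })
  }

  if (is.null(stimulation)) {
    stimulation <- stage("simulate", generate_cohort(config$cohort))
  } else {
    check_stim_table(stimulation)
  }
  write_stim_csv(stimulation, file.path(output_dir, "stimulation.csv"))

  built <- stage("preprocess", build_feature_table(
    stimulation, k = config$iqr_k, scope = config$iqr_scope))
  features <- built$features
  write_stim_csv(features, file.path(output_dir, "features.csv"))
  write_json_report(built$report[c("rows_in", "rows_removed", "rows_out", "k", "scope")],
                    file.path(output_dir, "cleaning_report.json"))

  dist_report <- stage("distfit", gamma_cell_report(features))
  utils::write.csv(dist_report, file.path(output_dir, "distribution_report.csv"),
                   row.names = FALSE)

  pg <- stage("glmm", pc_glmm_analysis(features, positive = config$positive_class))
  utils::write.csv(pg$aggregated, file.path(output_dir, "aggregated_pc1.csv"),
                   row.names = FALSE)
  glmm <- pg$glmm
  write_json_report(
    list(
      loadings = as.list(pg$pca$loadings),
      variance_explained = pg$pca$variance_explained,
      beta0 = glmm$beta0, beta1 = glmm$beta1,
      se0 = glmm$se0, se1 = glmm$se1, z0 = glmm$z0, z1 = glmm$z1,
      p0 = glmm$p0, p1 = glmm$p1,
      var_intercept = glmm$var_intercept, var_slope = glmm$var_slope,
      aic = glmm$aic, bic = glmm$bic, n_obs = glmm$n_obs,
      boundary = glmm$boundary, converged = glmm$converged
    ),
    file.path(output_dir, "glmm_summary.json")
  )

  cmp <- stage("classify", run_feature_set_comparison(
    features, k = config$cv_k, seed = config$cv_seed,
    positive = config$positive_class,
    group_by_subject = config$group_by_subject,
    n_estimators = config$n_estimators,
    learning_rate = config$learning_rate,
    max_depth = config$max_depth,
    keep_models = TRUE
  ))
  utils::write.csv(cmp$per_fold, file.path(output_dir, "per_fold_metrics.csv"),
                   row.names = FALSE)
  write_json_report(
    list(
      mean_metrics = cmp$mean_metrics,
      paired_tests = cmp$paired_tests,
      confusion = as.data.frame.matrix(unclass(cmp$confusion)),
      settings = cmp$settings
    ),
    file.path(output_dir, "comparison_report.json")
  )

  attr_report <- stage("attribution", attribution(cmp, features))
  utils::write.csv(attr_report$gini, file.path(output_dir, "gini_importance.csv"),
                   row.names = FALSE)
  shap_summary <- do.call(rbind, lapply(
    intersect(c("amplitude_uv", "isi_ms", "delta", "rho", "delta_rho"),
              names(attr_report$shap)),
    function(f) data.frame(feature = f,
                           mean_abs_shap = mean(abs(attr_report$shap[[f]])),
                           mean_shap = mean(attr_report$shap[[f]]))
  ))
  utils::write.csv(shap_summary, file.path(output_dir, "shap_summary.csv"),
                   row.names = FALSE)

  manifest <- list(
    package = "tmsmep",
    version = as.character(utils::packageVersion("tmsmep")),
    config = serialize_config(config),
    artifacts = c(
      "stimulation.csv", "features.csv", "cleaning_report.json",
      "distribution_report.csv", "aggregated_pc1.csv", "glmm_summary.json",
      "per_fold_metrics.csv", "comparison_report.json",
      "gini_importance.csv", "shap_summary.csv"
    )
  )
  write_json_report(manifest, file.path(output_dir, "manifest.json"))

  invisible(list(
    stimulation = stimulation, features = features,
    cleaning_report = built$report, distribution_report = dist_report,
    pc_glmm = pg, comparison = cmp, attribution = attr_report,
    manifest = manifest
  ))
}

serialize_config <- function(config) {
  ch <- config$cohort
  effects_as_list <- function(e) {
    e <- unclass(e)
    e$isi_modulation <- as.list(e$isi_modulation) # keep ISI keys in JSON
    e
  }
  list(
    cohort = list(
      n_mdd = ch$n_mdd, n_hc = ch$n_hc, seed = ch$seed,
      protocol = unclass(ch$protocol),
      effects_hc = effects_as_list(ch$effects_hc),
      effects_mdd = effects_as_list(ch$effects_mdd)
    ),
    iqr_k = config$iqr_k, iqr_scope = config$iqr_scope,
    cv_k = config$cv_k, cv_seed = config$cv_seed,
    positive_class = config$positive_class,
    group_by_subject = config$group_by_subject,
    n_estimators = config$n_estimators,
    learning_rate = config$learning_rate,
    max_depth = config$max_depth
  )
}

#' Read a run configuration from JSON
#'
#' Mirrors the manifest's `config` block, so a previous run's manifest can
#' seed a new identical run.
#'
#' @param path JSON file.
#' @return A [run_config()] object.
#' @export
read_run_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(j$config)) j <- j$config  # accept a whole manifest
  ch <- j$cohort
  cohort <- cohort_config(
    n_mdd = ch$n_mdd, n_hc = ch$n_hc, seed = ch$seed,
    protocol = do.call(protocol_spec, ch$protocol[
      c("isis_ms", "n_paired_per_isi", "n_single",
        "conditioning_intensity_pct_rmt", "test_intensity_pct_rmt")]),
    effects_hc = effects_from_json(ch$effects_hc),
    effects_mdd = effects_from_json(ch$effects_mdd)
  )
  run_config(
    cohort = cohort, iqr_k = j$iqr_k, iqr_scope = j$iqr_scope,
    cv_k = j$cv_k, cv_seed = j$cv_seed, positive_class = j$positive_class,
    group_by_subject = isTRUE(j$group_by_subject),
    n_estimators = j$n_estimators, learning_rate = j$learning_rate,
    max_depth = j$max_depth
  )
}

effects_from_json <- function(e) {
  group_effects(
    base_shape = e$base_shape, base_scale = e$base_scale,
    group_scale_factor = e$group_scale_factor,
    isi_modulation = unlist(e$isi_modulation),
    subject_scale_sd = e$subject_scale_sd
  )
}
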