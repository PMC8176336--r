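#' End-to-end analysis pipeline
#'
#' Runs the full chain on a synthetic cohort: simulate, preprocess (inclusion,
#' outlier filter, imputation, encoding), label, 5-fold cross-validate, train
#' the deployable model on the stratified 80% split and evaluate it on the
#' held-out 20%, optionally compute ablation feature importance, sweep
#' counterfactual dose recommendations and audit their direction. All
#' artifacts are written to `out_dir` as delimited tables / JSON together
#' with a manifest recording seeds and stage counts; a rerun with the same
#' configuration reproduces them exactly.
#'
#' All randomness derives from `seed`: the generator uses `seed` and the
#' training stages use `seed + 1`.
#'
#' @param out_dir output directory.
#' @param n_patients cohort size.
#' @param dialect `"mimic"` or `"pumch"`.
#' @param seed global integer seed.
#' @param epochs,learning_rate training hyperparameters (defaults 5000 and
#'   0.015).
#' @param cv_folds number of cross-validation folds.
#' @param grid_steps dose-grid resolution for the recommendation sweep.
#' @param importance logical; ablation importance retrains the model once per
#'   feature and dominates runtime, so it can be disabled.
#' @return Invisibly, a list with the cohort, dataset, CV results, model,
#'   test metrics, recommendations, audit and (optionally) importance report.
#' @export
run_pipeline <- function(out_dir, n_patients = 1000, dialect = "mimic",
                         seed = 1L, epochs = 5000, learning_rate = 0.015,
                         cv_folds = 5, grid_steps = 200, importance = FALSE) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  gcfg <- generator_config(n_patients, dialect, seed = seed)
  cohort <- generate_cohort(gcfg)
  write_cohort(cohort, out_dir)

  dataset <- preprocess_cohort(cohort)
  tcfg <- train_config(epochs = epochs, learning_rate = learning_rate,
                       seed = seed + 1L, cv_folds = cv_folds)

  cv <- cross_validate(dataset, tcfg)

  split <- stratified_split(dataset$rows$label, tcfg$train_fraction, tcfg$seed)
  model <- train_network(dataset, tcfg, rows_idx = split$train)
  test_rows <- dataset$rows[split$test, , drop = FALSE]
  test_pred <- predict_classes(model, test_rows)
  test_metrics <- compute_metrics(confusion_matrix3(test_rows$label, test_pred))
  write_model(model, file.path(out_dir, "model.json"))

  imp <- NULL
  if (importance) {
    imp <- feature_importance(dataset, tcfg)
    utils::write.csv(as.data.frame(imp)[, c("feature", "E_i", "A", "A_i", "rank")],
                     file.path(out_dir, "importance.csv"), row.names = FALSE)
  }

  train_max_dose <- max(dataset$rows$total_dose[split$train])
  grid <- dose_grid(train_max_dose, grid_steps)
  recs <- recommend_doses(model, test_rows, grid)
  audit <- audit_recommendations(recs, by = "predicted")
  utils::write.csv(recs, file.path(out_dir, "recommendations.csv"), row.names = FALSE)

  report <- list(
    preprocessing = dataset$report[c("exclusion_tally", "n_missing_removed",
                                     "n_outlier_removed", "n_imputed", "n_final")],
    cv_mean = as.list(cv$mean),
    test_metrics = unclass(test_metrics),
    audit = audit
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("hepadose")),
    seed = seed, generator_seed = seed, training_seed = seed + 1L,
    dialect = dialect,
    stage_counts = list(generated = n_patients,
                        included = dataset$report$exclusion_tally$included,
                        after_missing_removal =
                          dataset$report$exclusion_tally$included - dataset$report$n_missing_removed,
                        after_outlier_removal = dataset$report$n_final,
                        train = length(split$train), test = length(split$test)),
    outlier_bounds = dataset$report$outlier_bounds,
    fold_sizes = as.list(table(cv$folds))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)

  invisible(list(cohort = cohort, dataset = dataset, cv = cv, model = model,
                 test_metrics = test_metrics, recommendations = recs,
                 audit = audit, importance = imp))
}
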