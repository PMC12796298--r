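#' Feature sets for the diagnostic classifiers
#'
#' The three classifiers compared by [run_feature_set_comparison()] share
#' hyperparameters and cross-validation splits but see different columns:
#' raw MEP amplitude plus ISI (`mep_isi`), the excitability ratios plus ISI
#' (`deltarho_isi`), or everything (`all`).
#'
#' @param name One of `"mep_isi"`, `"deltarho_isi"`, `"all"`.
#' @return A list with `name` and `columns`.
#' @export
feature_set_spec <- function(name = c("mep_isi", "deltarho_isi", "all")) {
  name <- match.arg(name)
  columns <- switch(name,
    mep_isi = c("amplitude_uv", "isi_ms"),
    deltarho_isi = c("delta", "rho", "isi_ms"),
    all = c("amplitude_uv", "isi_ms", "delta", "rho")
  )
  list(name = name, columns = columns)
}

#' Fit a gradient-boosted decision-tree classifier
#'
#' Binary gradient boosting with logistic loss via [xgboost::xgb.train()],
#' single-threaded and seeded for reproducibility. Defaults are 250 trees,
#' learning rate 0.1 and maximum depth 8.
#'
#' @param data Feature table holding the training rows.
#' @param feature_cols Columns used as predictors.
#' @param positive Label encoded as 1.
#' @param n_estimators,learning_rate,max_depth Boosting hyperparameters.
#' @param seed Seed passed to the booster.
#' @return An object of class `gbdt_model` supporting [predict_gbdt()],
#'   [shap_values()] and [gini_importance()].
#' @export
fit_gbdt <- function(data, feature_cols, positive = "MDD",
                     n_estimators = 250L, learning_rate = 0.1,
                     max_depth = 8L, seed = 0L) {
  check_stim_table(data, require = c(feature_cols, "group"))
  y <- as.integer(data$group == positive)
  if (length(unique(y)) < 2L) stop_param("training labels contain a single class")
  x <- as.matrix(data[feature_cols])
  storage.mode(x) <- "double"
  dm <- xgboost::xgb.DMatrix(x, label = y)
  booster <- xgboost::xgb.train(
    params = list(
      objective = "binary:logistic",
      eta = learning_rate,
      max_depth = as.integer(max_depth),
      nthread = 1L,
      seed = as.integer(seed)
    ),
    data = dm,
    nrounds = as.integer(n_estimators),
    verbose = 0
  )
  negative <- setdiff(unique(data$group), positive)
  structure(
    list(booster = booster, feature_cols = feature_cols,
         positive = positive, negative = negative[1]),
    class = "gbdt_model"
  )
}

model_matrix <- function(model, data) {
  x <- as.matrix(data[model$feature_cols])
  storage.mode(x) <- "double"
  xgboost::xgb.DMatrix(x)
}

#' Predict from a fitted gradient-boosting model
#'
#' @param model A `gbdt_model`.
#' @param data Rows to score.
#' @param type `"prob"` (positive-class probability), `"label"` (threshold
#'   0.5) or `"margin"` (log-odds).
#' @param threshold Probability cut-off for `type = "label"`.
#' @return Numeric vector, or character labels for `type = "label"`.
#' @export
predict_gbdt <- function(model, data, type = c("prob", "label", "margin"),
                         threshold = 0.5) {
  stopifnot(inherits(model, "gbdt_model"))
  type <- match.arg(type)
  dm <- model_matrix(model, data)
  if (type == "margin") {
    return(as.numeric(predict(model$booster, dm, outputmargin = TRUE)))
  }
  p <- as.numeric(predict(model$booster, dm))
  if (type == "prob") return(p)
  ifelse(p >= threshold, model$positive, model$negative)
}

#' Per-row SHAP attributions of a tree ensemble
#'
#' Tree-path-dependent Shapley values for each feature and row on the margin
#' (log-odds) scale, computed in double precision from the booster's tree
#' structures (cover-weighted conditional expectations, the standard
#' TreeSHAP recursion). Rows satisfy local accuracy: `bias` (the model's
#' expected margin) plus the feature contributions equals `margin` to
#' numerical round-off.
#'
#' @param model A `gbdt_model`.
#' @param data Rows to explain.
#' @return Data.frame with one column per feature, a `bias` column and the
#'   model `margin`.
#' @export
shap_values <- function(model, data) {
  stopifnot(inherits(model, "gbdt_model"))
  x <- as.matrix(data[model$feature_cols])
  storage.mode(x) <- "double"
  trees <- booster_trees(model)
  phi <- .tree_shap_cpp(trees, x)
  contrib <- as.data.frame(phi)
  names(contrib) <- c(model$feature_cols, "bias")
  base <- base_margin(model)
  contrib$bias <- contrib$bias + base
  contrib$margin <- as.numeric(.tree_margin_cpp(trees, x)) + base
  contrib
}

# Parse the booster dump into flat per-tree node arrays (0-based node ids
# and feature indices) for the C++ TreeSHAP/margin kernels.
booster_trees <- function(model) {
  dt <- as.data.frame(xgboost::xgb.model.dt.tree(model = model$booster))
  node_of <- function(id) as.integer(sub("^\\d+-", "", id))
  lapply(split(dt, dt$Tree), function(tr) {
    tr <- tr[order(tr$Node), , drop = FALSE]
    is_leaf <- tr$Feature == "Leaf"
    list(
      feature = as.integer(ifelse(is_leaf, -1L,
                                  match(tr$Feature, model$feature_cols) - 1L)),
      split = as.numeric(ifelse(is_leaf, 0, tr$Split)),
      yes = as.integer(ifelse(is_leaf, 0L, node_of(tr$Yes))),
      no = as.integer(ifelse(is_leaf, 0L, node_of(tr$No))),
      missing = as.integer(ifelse(is_leaf, 0L, node_of(tr$Missing))),
      cover = as.numeric(tr$Cover),
      value = as.numeric(ifelse(is_leaf, tr$Gain, 0)) # leaf values live in Gain
    )
  })
}

# Global margin offset: logit of the booster's fitted base score.
base_margin <- function(model) {
  cfg <- xgboost::xgb.config(model$booster)
  stats::qlogis(as.numeric(cfg$learner$learner_model_param$base_score))
}

#' Gini (gain) feature importance of a tree ensemble
#'
#' Total loss reduction contributed by splits on each feature, normalised to
#' sum to 1 over the model's features; features never used by any split get
#' exactly 0.
#'
#' @param model A `gbdt_model`.
#' @return Named numeric vector over `model$feature_cols`.
#' @export
gini_importance <- function(model) {
  stopifnot(inherits(model, "gbdt_model"))
  imp <- xgboost::xgb.importance(model = model$booster)
  out <- setNames(rep(0, length(model$feature_cols)), model$feature_cols)
  if (!is.null(imp) && nrow(imp) > 0L) {
    out[imp$Feature] <- imp$Gain
  }
  out
}

#' Cross-validated comparison of the three feature sets
#'
#' Trains the three gradient-boosting models ([feature_set_spec()]) on
#' identical stratified cross-validation splits, evaluates the eight metrics
#' of [classification_metrics()] on every held-out fold, averages them
#' across folds, and runs two-sided paired t-tests (pairing on fold) between
#' consecutive models: `mep_isi` vs `deltarho_isi` and `deltarho_isi` vs
#' `all`. A metric whose fold-wise differences are all zero is reported with
#' p = 1 and a `zero_variance` flag. Also pools the held-out hard
#' predictions of the all-features model into a row-normalised confusion
#' matrix.
#'
#' Rows (individual stimulations) are the cross-validation unit by default,
#' stratified on diagnosis only, so a subject's pulses can appear in both
#' train and test folds; `group_by_subject = TRUE` instead assigns whole
#' subjects to folds (stratified on diagnosis) as a leakage-free robustness
#' mode.
#'
#' @param features Feature table (from [build_feature_table()]).
#' @param k Number of folds.
#' @param seed Seed for the fold assignment and boosters.
#' @param positive Positive class label.
#' @param group_by_subject Assign whole subjects to folds.
#' @param n_estimators,learning_rate,max_depth Booster hyperparameters.
#' @param keep_models Keep fitted per-fold models (needed for
#'   [attribution()]).
#' @return An object of class `mep_comparison`: `per_fold` (long metric
#'   table), `mean_metrics`, `paired_tests`, `confusion` (row-normalised,
#'   all-features model), `folds` (row fold ids), `models` and `settings`.
#' @export
run_feature_set_comparison <- function(features, k = 10L, seed = 1L,
                                       positive = "MDD",
                                       group_by_subject = FALSE,
                                       n_estimators = 250L,
                                       learning_rate = 0.1,
                                       max_depth = 8L,
                                       keep_models = TRUE) {
  check_stim_table(features,
    require = c("subject_id", "group", "isi_ms", "amplitude_uv", "delta", "rho"))
  if (!group_by_subject) {
    folds <- stratified_folds(features$group, k = k, seed = seed)
  } else {
    subjects <- unique(features[c("subject_id", "group")])
    sf <- stratified_folds(subjects$group, k = k, seed = seed)
    folds <- sf[match(features$subject_id, subjects$subject_id)]
  }
  set_names <- c("mep_isi", "deltarho_isi", "all")
  specs <- lapply(set_names, feature_set_spec)
  names(specs) <- set_names

  per_fold <- list()
  models <- lapply(specs, function(s) vector("list", k))
  conf_true <- character(0)
  conf_pred <- character(0)

  for (fold in seq_len(k)) {
    test <- folds == fold
    train_rows <- features[!test, , drop = FALSE]
    test_rows <- features[test, , drop = FALSE]
    for (s in specs) {
      model <- fit_gbdt(train_rows, s$columns, positive = positive,
                        n_estimators = n_estimators,
                        learning_rate = learning_rate,
                        max_depth = max_depth, seed = seed)
      score <- predict_gbdt(model, test_rows, type = "prob")
      pred <- ifelse(score >= 0.5, positive,
                     setdiff(unique(features$group), positive)[1])
      m <- classification_metrics(test_rows$group, pred, score,
                                  positive = positive)
      per_fold[[length(per_fold) + 1L]] <- data.frame(
        model = s$name, fold = fold, t(m),
        stringsAsFactors = FALSE
      )
      if (keep_models) models[[s$name]][[fold]] <- model
      if (s$name == "all") {
        conf_true <- c(conf_true, test_rows$group)
        conf_pred <- c(conf_pred, pred)
      }
    }
  }
  per_fold <- do.call(rbind, per_fold)
  metric_names <- setdiff(names(per_fold), c("model", "fold"))
  mean_metrics <- aggregate(per_fold[metric_names],
                            by = list(model = per_fold$model), FUN = mean)
  mean_metrics <- mean_metrics[match(set_names, mean_metrics$model), , drop = FALSE]
  rownames(mean_metrics) <- NULL

  tests <- paired_fold_tests(
    per_fold, metric_names,
    list(c("mep_isi", "deltarho_isi"), c("deltarho_isi", "all"))
  )

  lv <- sort(unique(features$group))
  conf <- table(factor(conf_true, levels = lv), factor(conf_pred, levels = lv))
  conf <- prop.table(conf, margin = 1)

  structure(
    list(
      per_fold = per_fold,
      mean_metrics = mean_metrics,
      paired_tests = tests,
      confusion = conf,
      folds = folds,
      models = if (keep_models) models else NULL,
      settings = list(k = k, seed = seed, positive = positive,
                      group_by_subject = group_by_subject,
                      n_estimators = n_estimators,
                      learning_rate = learning_rate, max_depth = max_depth)
    ),
    class = "mep_comparison"
  )
}

# Two-sided paired t-tests per metric between model pairs, pairing on fold.
# An all-zero difference vector has no variance to test; it is reported as
# p = 1 with a zero_variance flag.
paired_fold_tests <- function(per_fold, metric_names, comparisons) {
  tests <- do.call(rbind, lapply(comparisons, function(cmp) {
    do.call(rbind, lapply(metric_names, function(metric) {
      a <- per_fold[per_fold$model == cmp[1], metric]
      b <- per_fold[per_fold$model == cmp[2], metric]
      d <- b - a
      # constant differences (all-equal metric vectors included) leave the
      # paired t statistic undefined
      if (sd(d) <= .Machine$double.eps^0.5 * max(1, abs(mean(d)))) {
        data.frame(comparison = paste(cmp, collapse = " vs "), metric = metric,
                   mean_difference = mean(d), t_statistic = NA_real_,
                   p_value = 1, zero_variance = TRUE,
                   stringsAsFactors = FALSE)
      } else {
        tt <- t.test(b, a, paired = TRUE)
        data.frame(comparison = paste(cmp, collapse = " vs "), metric = metric,
                   mean_difference = mean(d),
                   t_statistic = unname(tt$statistic),
                   p_value = tt$p.value, zero_variance = FALSE,
                   stringsAsFactors = FALSE)
      }
    }))
  }))
  rownames(tests) <- NULL
  tests
}

#' @export
print.mep_comparison <- function(x, ...) {
  cat(sprintf("Feature-set comparison (%d-fold stratified CV, seed %d)\n",
              x$settings$k, x$settings$seed))
  cat("\nFold-averaged metrics:\n")
  mm <- x$mean_metrics
  mm[-1] <- lapply(mm[-1], round, 3)
  print(mm, row.names = FALSE)
  cat("\nPaired t-tests (fold-wise):\n")
  pt <- x$paired_tests
  pt$mean_difference <- round(pt$mean_difference, 3)
  pt$p_value <- signif(pt$p_value, 3)
  print(pt[c("comparison", "metric", "mean_difference", "p_value")],
        row.names = FALSE)
  cat("\nRow-normalised confusion matrix (all-features model, pooled folds):\n")
  print(round(x$confusion, 3))
  invisible(x)
}

#' SHAP and Gini attribution across cross-validation folds
#'
#' For the all-features model, computes SHAP values on each fold's held-out
#' rows and pools them; because `delta` and `rho` are collinear their
#' contributions are additionally summed into one combined column. For every
#' model, per-fold Gini (gain) importances are averaged across folds.
#'
#' @param comparison A [run_feature_set_comparison()] result with
#'   `keep_models = TRUE`.
#' @param features The feature table the comparison was run on.
#' @return An object of class `mep_attribution`: `shap` (pooled held-out
#'   SHAP table with `row`, `fold`, per-feature columns, `delta_rho`
#'   combined, `bias`, `margin`, and the feature values prefixed
#'   `value_`) and `gini` (model x feature fold-averaged importances).
#' @export
attribution <- function(comparison, features) {
  stopifnot(inherits(comparison, "mep_comparison"))
  if (is.null(comparison$models)) {
    stop_param("comparison was run with keep_models = FALSE")
  }
  folds <- comparison$folds
  k <- comparison$settings$k

  shap <- do.call(rbind, lapply(seq_len(k), function(fold) {
    model <- comparison$models[["all"]][[fold]]
    rows <- which(folds == fold)
    sv <- shap_values(model, features[rows, , drop = FALSE])
    sv$delta_rho <- sv$delta + sv$rho
    sv$row <- rows
    sv$fold <- fold
    vals <- features[rows, model$feature_cols, drop = FALSE]
    names(vals) <- paste0("value_", names(vals))
    cbind(sv, vals)
  }))
  rownames(shap) <- NULL

  gini <- do.call(rbind, lapply(names(comparison$models), function(mn) {
    per_fold <- vapply(
      comparison$models[[mn]], gini_importance,
      numeric(length(comparison$models[[mn]][[1]]$feature_cols))
    )
    data.frame(model = mn, feature = rownames(per_fold),
               gini = rowMeans(per_fold), stringsAsFactors = FALSE)
  }))
  rownames(gini) <- NULL

  structure(list(shap = shap, gini = gini), class = "mep_attribution")
}

#' @export
print.mep_attribution <- function(x, ...) {
  cat("Fold-averaged Gini importances:\n")
  g <- x$gini
  g$gini <- round(g$gini, 3)
  print(g, row.names = FALSE)
  feats <- intersect(c("amplitude_uv", "isi_ms", "delta", "rho", "delta_rho"),
                     names(x$shap))
  cat("\nMean |SHAP| on held-out rows (margin scale):\n")
  print(round(vapply(x$shap[feats], function(v) mean(abs(v)), numeric(1)), 4))
  invisible(x)
}
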