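# Brute-force contingency oracles, written independently of the package
# implementation.
oracle_metrics <- function(y, p, positive) {
  tp <- sum(y == positive & p == positive)
  tn <- sum(y != positive & p != positive)
  fp <- sum(y != positive & p == positive)
  fn <- sum(y == positive & p != positive)
  n <- tp + tn + fp + fn
  po <- (tp + tn) / n
  pe <- ((tp + fp) / n) * ((tp + fn) / n) + ((tn + fn) / n) * ((tn + fp) / n)
  list(
    accuracy = po,
    balanced = 0.5 * (tp / (tp + fn) + tn / (tn + fp)),
    kappa = if (pe == 1) 0 else (po - pe) / (1 - pe),
    mcc = {
      den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
      if (den == 0) 0 else (tp * tn - fp * fn) / den
    },
    f1 = 2 * tp / (2 * tp + fp + fn),
    recall = tp / (tp + fn)
  )
}

oracle_roc_auc <- function(y, s, positive) {
  sp <- s[y == positive]
  sn <- s[y != positive]
  total <- 0
  for (a in sp) total <- total + sum(a > sn) + 0.5 * sum(a == sn)
  total / (length(sp) * length(sn))
}

test_that("stratified folds are balanced, deterministic and guarded", {
  labels <- rep(c("MDD", "HC"), c(60, 40))
  f <- stratified_folds(labels, k = 10, seed = 7)
  for (i in 1:10) {
    expect_equal(sum(f == i & labels == "MDD"), 6L)
    expect_equal(sum(f == i & labels == "HC"), 4L)
  }
  expect_identical(f, stratified_folds(labels, k = 10, seed = 7))
  expect_false(identical(f, stratified_folds(labels, k = 10, seed = 8)))
  expect_error(stratified_folds(rep(c("a", "b"), c(9, 91)), k = 10), ">= k")
})

test_that("fold sizes and class proportions stay within one of parity", {
  set.seed(71)
  for (i in 1:20) {
    n <- sample(50:400, 1)
    labels <- sample(c("MDD", "HC"), n, replace = TRUE, prob = c(0.6, 0.4))
    k <- sample(3:10, 1)
    if (min(table(labels)) < k) next
    f <- stratified_folds(labels, k = k, seed = i)
    sizes <- tabulate(f, nbins = k)
    expect_lte(max(sizes) - min(sizes), 1L)
    for (cl in c("MDD", "HC")) {
      cc <- tabulate(f[labels == cl], nbins = k)
      expect_lte(max(cc) - min(cc), 1L)
    }
  }
})

test_that("the worked confusion matrix yields the documented metrics", {
  y <- rep(c("HC", "MDD"), c(50, 50))
  p <- c(rep("HC", 40), rep("MDD", 10), rep("HC", 5), rep("MDD", 45))
  s <- ifelse(p == "MDD", 0.9, 0.1)
  m <- classification_metrics(y, p, s)
  expect_equal(unname(m["accuracy"]), 0.85, tolerance = 1e-12)
  expect_equal(unname(m["balanced_accuracy"]), 0.85, tolerance = 1e-12)
  expect_equal(unname(m["cohen_kappa"]), 0.70, tolerance = 1e-12)
  expect_equal(unname(m["mcc"]), 1750 / sqrt(55 * 50 * 50 * 45), tolerance = 1e-12)
  expect_equal(unname(m["f1"]), 90 / 105, tolerance = 1e-12)
  expect_equal(unname(m["recall"]), 0.90, tolerance = 1e-12)
})

test_that("perfect and degenerate predictors hit their closed forms", {
  y <- rep(c("HC", "MDD"), c(3, 5))
  perfect <- classification_metrics(y, y, ifelse(y == "MDD", 1, 0))
  expect_true(all(abs(perfect - 1) < 1e-12))

  all_pos <- classification_metrics(y, rep("MDD", 8), rep(0.9, 8))
  expect_equal(unname(all_pos["balanced_accuracy"]), 0.5, tolerance = 1e-12)
  expect_equal(unname(all_pos["cohen_kappa"]), 0, tolerance = 1e-12)
  expect_equal(unname(all_pos["mcc"]), 0, tolerance = 1e-12)

  expect_error(classification_metrics(rep("MDD", 4), y[1:4], 1:4), "both classes")
})

test_that("metrics match brute-force oracles on random instances", {
  set.seed(72)
  for (i in 1:200) {
    n <- sample(20:60, 1)
    y <- sample(c("HC", "MDD"), n, replace = TRUE)
    if (length(unique(y)) < 2) next
    p <- sample(c("HC", "MDD"), n, replace = TRUE)
    s <- round(runif(n), 1) # coarse scores force ties
    m <- classification_metrics(y, p, s)
    o <- oracle_metrics(y, p, "MDD")
    expect_equal(unname(m["cohen_kappa"]), o$kappa, tolerance = 1e-12)
    expect_equal(unname(m["mcc"]), o$mcc, tolerance = 1e-12)
    expect_equal(unname(m["f1"]), o$f1, tolerance = 1e-12)
    expect_equal(unname(m["balanced_accuracy"]), o$balanced, tolerance = 1e-12)
    expect_equal(unname(m["roc_auc"]), oracle_roc_auc(y, s, "MDD"),
                 tolerance = 1e-12)
  }
})

test_that("ROC-AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(73)
  y <- sample(c("HC", "MDD"), 200, replace = TRUE)
  s <- rnorm(200) + (y == "MDD")
  m <- classification_metrics(y, ifelse(s > 0.5, "MDD", "HC"), s)
  ref <- as.numeric(pROC::auc(pROC::roc(response = y, predictor = s,
                                        levels = c("HC", "MDD"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(unname(m["roc_auc"]), ref, tolerance = 1e-12)
})

separable_features <- function(n = 120, seed = 74) {
  set.seed(seed)
  g <- rep(c("HC", "MDD"), each = n / 2)
  data.frame(
    subject_id = sprintf("s%03d", seq_len(n)), session_id = "x", group = g,
    isi_ms = sample(c(0L, 4L, 10L), n, TRUE),
    amplitude_uv = ifelse(g == "MDD", runif(n, 10, 20), runif(n, 30, 40)),
    delta = runif(n), rho = runif(n), stringsAsFactors = FALSE
  )
}

test_that("the booster separates separable data and refits deterministically", {
  feats <- separable_features()
  model <- fit_gbdt(feats, c("amplitude_uv", "isi_ms"), n_estimators = 30L)
  pred <- predict_gbdt(model, feats, type = "label")
  expect_equal(mean(pred == feats$group), 1)

  p1 <- predict_gbdt(model, feats, type = "prob")
  model2 <- fit_gbdt(feats, c("amplitude_uv", "isi_ms"), n_estimators = 30L)
  expect_identical(p1, predict_gbdt(model2, feats, type = "prob"))

  single <- feats[feats$group == "MDD", ]
  expect_error(fit_gbdt(single, c("amplitude_uv", "isi_ms")), "single class")
})

test_that("SHAP attributions satisfy local accuracy and ignore unused features", {
  feats <- separable_features(n = 100, seed = 75)
  feats$dead <- 1 # constant column can never be split on
  model <- fit_gbdt(feats, c("amplitude_uv", "dead"), n_estimators = 40L)
  sv <- shap_values(model, feats)
  resid <- abs(sv$bias + sv$amplitude_uv + sv$dead - sv$margin)
  expect_true(all(resid <= 1e-6 * pmax(1, abs(sv$margin))))
  expect_true(all(sv$dead == 0))

  g <- gini_importance(model)
  expect_equal(sum(g), 1, tolerance = 1e-9)
  expect_equal(unname(g["dead"]), 0)
  expect_true(all(g >= 0))
})

test_that("TreeSHAP agrees with the booster's own contribution algorithm", {
  feats <- small_features(seed = 78L)
  model <- fit_gbdt(feats, c("amplitude_uv", "isi_ms", "delta", "rho"),
                    n_estimators = 60L, max_depth = 5L)
  sub <- feats[seq(1, nrow(feats), by = 4), ]
  sv <- shap_values(model, sub)

  dm <- tmsmep:::model_matrix(model, sub)
  ref <- as.data.frame(predict(model$booster, dm, predcontrib = TRUE))
  for (f in c("amplitude_uv", "isi_ms", "delta", "rho")) {
    expect_equal(sv[[f]], ref[[f]], tolerance = 1e-4)
  }
  expect_equal(sv$bias, ref[[ncol(ref)]], tolerance = 1e-4)
  # margins agree with the booster's single-precision output
  xm <- as.numeric(predict(model$booster, dm, outputmargin = TRUE))
  expect_equal(sv$margin, xm, tolerance = 1e-4)
  # and the additive identity is exact in double precision
  resid <- abs(sv$bias + sv$amplitude_uv + sv$isi_ms + sv$delta + sv$rho -
                 sv$margin)
  expect_lt(max(resid), 1e-10)
})

test_that("paired fold tests apply the zero-variance convention", {
  per_fold <- data.frame(
    model = rep(c("mep_isi", "deltarho_isi"), each = 4),
    fold = rep(1:4, 2),
    accuracy = c(0.5, 0.6, 0.55, 0.5, 0.7, 0.85, 0.71, 0.74),
    flat = rep(0.5, 8)
  )
  tests <- tmsmep:::paired_fold_tests(per_fold, c("accuracy", "flat"),
                                      list(c("mep_isi", "deltarho_isi")))
  acc <- tests[tests$metric == "accuracy", ]
  flat <- tests[tests$metric == "flat", ]
  expect_false(acc$zero_variance)
  expect_equal(acc$p_value,
               t.test(per_fold$accuracy[5:8], per_fold$accuracy[1:4],
                      paired = TRUE)$p.value)
  expect_true(flat$zero_variance)
  expect_equal(flat$p_value, 1)
})

test_that("a small comparison run shares splits and reports all pieces", {
  feats <- small_features(seed = 76L)
  cmp <- run_feature_set_comparison(feats, k = 3L, seed = 5L,
                                    n_estimators = 25L, max_depth = 3L)
  expect_equal(sort(unique(cmp$per_fold$model)),
               sort(c("mep_isi", "deltarho_isi", "all")))
  expect_equal(nrow(cmp$per_fold), 9L)
  # identical fold assignment for the three models, by construction; the
  # stored vector covers every row exactly once
  expect_equal(length(cmp$folds), nrow(feats))
  expect_setequal(unique(cmp$folds), 1:3)
  # fold means bracket the per-fold values
  for (mn in unique(cmp$per_fold$model)) {
    v <- cmp$per_fold$balanced_accuracy[cmp$per_fold$model == mn]
    mm <- cmp$mean_metrics$balanced_accuracy[cmp$mean_metrics$model == mn]
    expect_gte(mm, min(v))
    expect_lte(mm, max(v))
  }
  expect_equal(nrow(cmp$paired_tests), 16L) # 8 metrics x 2 comparisons
  expect_equal(unname(rowSums(cmp$confusion)), c(1, 1), tolerance = 1e-12)

  att <- attribution(cmp, feats)
  expect_setequal(att$shap$row, seq_len(nrow(feats)))
  for (mn in unique(att$gini$model)) {
    expect_equal(sum(att$gini$gini[att$gini$model == mn]), 1, tolerance = 1e-9)
  }
})

test_that("subject-grouped CV keeps each subject's rows in one fold", {
  feats <- small_features(seed = 77L)
  cmp <- run_feature_set_comparison(feats, k = 3L, seed = 2L,
                                    group_by_subject = TRUE,
                                    n_estimators = 10L, max_depth = 3L,
                                    keep_models = FALSE)
  spread <- tapply(cmp$folds, feats$subject_id, function(v) length(unique(v)))
  expect_true(all(spread == 1L))
})
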