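#' Stratified cross-validation fold assignment
#'
#' Assigns each row to one of `k` folds so that fold sizes differ by at most
#' one and each class is represented in every fold within one of its
#' proportional share. Deterministic given `seed`; the caller's RNG state is
#' preserved.
#'
#' @param labels Class label per row.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold ids (1..k) per row.
#' @export
stratified_folds <- function(labels, k = 10L, seed = 1L) {
  k <- check_scalar_count(k, "k", min = 2L)
  counts <- table(labels)
  if (any(counts < k)) {
    stop_param("every class needs >= k members; smallest class has ",
               min(counts), " < ", k)
  }
  with_preserved_seed(seed, {
    fold <- integer(length(labels))
    load <- integer(k)
    for (cl in names(counts)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      n_c <- length(idx)
      per <- rep(n_c %/% k, k)
      extra <- n_c %% k
      if (extra > 0L) {
        # park remainders on the currently lightest folds (random tie-break)
        ord <- order(load, sample.int(k))
        per[ord[seq_len(extra)]] <- per[ord[seq_len(extra)]] + 1L
      }
      fold[idx] <- rep.int(seq_len(k), per)
      load <- load + per
    }
    fold
  })
}

#' Binary classification metrics
#'
#' Computes the eight evaluation metrics used throughout the package from
#' true labels, hard predictions and continuous scores: accuracy, balanced
#' accuracy (mean per-class recall), Cohen's kappa, Matthews correlation
#' coefficient (MCC), F1, recall, ROC-AUC and the area under the
#' precision-recall curve. ROC-AUC uses the rank (Mann-Whitney) formulation
#' with half credit for ties; PR-AUC is the interpolation-free step sum
#' (average precision). Kappa and MCC return 0 when their denominator is
#' zero.
#'
#' @param y_true True labels.
#' @param y_pred Predicted labels.
#' @param y_score Numeric score for the positive class (higher = more
#'   positive).
#' @param positive Positive-class label; drives recall, F1 and the curves.
#' @return Named numeric vector with elements `accuracy`,
#'   `balanced_accuracy`, `cohen_kappa`, `mcc`, `f1`, `recall`, `roc_auc`,
#'   `pr_auc`.
#' @examples
#' y <- rep(c("HC", "MDD"), c(50, 50))
#' p <- rep(c("HC", "MDD", "HC", "MDD"), c(40, 10, 5, 45))
#' classification_metrics(y, p, ifelse(p == "MDD", 0.9, 0.1))
#' @export
classification_metrics <- function(y_true, y_pred, y_score, positive = "MDD") {
  n <- length(y_true)
  if (length(y_pred) != n || length(y_score) != n) {
    stop_param("`y_true`, `y_pred` and `y_score` must be aligned")
  }
  pos <- y_true == positive
  if (all(pos) || !any(pos)) {
    stop_param("`y_true` must contain both classes")
  }
  ppos <- y_pred == positive
  tp <- sum(pos & ppos); fn <- sum(pos & !ppos)
  fp <- sum(!pos & ppos); tn <- sum(!pos & !ppos)

  accuracy <- (tp + tn) / n
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  balanced <- (sens + spec) / 2
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  f1 <- if (precision + sens > 0) 2 * precision * sens / (precision + sens) else 0

  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  kappa <- if (pe == 1) 0 else (accuracy - pe) / (1 - pe)

  mcc_den <- sqrt(as.numeric(tp + fp)) * sqrt(as.numeric(tp + fn)) *
    sqrt(as.numeric(tn + fp)) * sqrt(as.numeric(tn + fn))
  mcc <- if (mcc_den == 0) 0 else
    (as.numeric(tp) * tn - as.numeric(fp) * fn) / mcc_den

  c(
    accuracy = accuracy, balanced_accuracy = balanced,
    cohen_kappa = kappa, mcc = mcc, f1 = f1, recall = sens,
    roc_auc = roc_auc(pos, y_score), pr_auc = pr_auc(pos, y_score)
  )
}

# Rank (Mann-Whitney) ROC-AUC; average ranks give half credit to ties.
roc_auc <- function(is_pos, score) {
  n_pos <- sum(is_pos)
  n_neg <- sum(!is_pos)
  r <- rank(score, ties.method = "average")
  (sum(r[is_pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# Interpolation-free step summation: sum over descending-score thresholds of
# precision x increment in recall, processing tied scores as one threshold.
pr_auc <- function(is_pos, score) {
  ord <- order(score, decreasing = TRUE)
  s <- score[ord]
  y <- is_pos[ord]
  last_of_group <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(y)[last_of_group]
  fp <- cumsum(!y)[last_of_group]
  n_pos <- sum(is_pos)
  rec <- tp / n_pos
  prec <- tp / (tp + fp)
  sum(diff(c(0, rec)) * prec)
}
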