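#' Majority vote of four base learners
#'
#' Combines per-learner hard labels by modal vote; 2--2 ties go to class 1
#' when the mean predicted probability for class 1 exceeds 0.5, otherwise to
#' class 0. The ensemble probability (used for ROC-AUC) is the mean of the
#' four learners' probabilities.
#'
#' @param labels `n x 4` matrix of 0/1 labels, one column per learner.
#' @param probs `n x 4` matrix of class-1 probabilities, aligned with
#'   `labels`.
#' @return A list with `label` (integer vector) and `prob` (numeric vector).
#' @export
majority_vote <- function(labels, probs) {
  labels <- as.matrix(labels)
  probs <- as.matrix(probs)
  if (ncol(labels) != 4 || !all(dim(labels) == dim(probs))) {
    abort("majority_vote: need aligned n x 4 label and probability matrices")
  }
  votes <- rowSums(labels)
  mean_p <- rowMeans(probs)
  label <- ifelse(votes > 2, 1L, ifelse(votes < 2, 0L,
                  ifelse(mean_p > 0.5, 1L, 0L)))
  list(label = as.integer(label), prob = mean_p)
}

#' Classification scores for one set of predictions
#'
#' Accuracy, precision, recall and F1 from the confusion counts (class 1 is
#' the positive class), plus ROC-AUC computed as the Wilcoxon--Mann--Whitney
#' rank statistic on the predicted probabilities.
#'
#' @param truth 0/1 vector of true labels.
#' @param label 0/1 vector of predicted labels.
#' @param prob Numeric vector of class-1 probabilities (for AUC).
#' @return A one-row tibble `accuracy, precision, recall, f1, auc, tp, tn,
#'   fp, fn, n`. `auc` is `NA` (flagged, not 0) when the truth is
#'   single-class; `precision`/`f1` are `NA` when no positive was predicted.
#' @export
score_predictions <- function(truth, label, prob = NULL) {
  stopifnot(length(truth) == length(label))
  tp <- sum(truth == 1 & label == 1)
  tn <- sum(truth == 0 & label == 0)
  fp <- sum(truth == 0 & label == 1)
  fn <- sum(truth == 1 & label == 0)
  precision <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  recall <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    NA_real_
  } else {
    2 * precision * recall / (precision + recall)
  }
  auc <- if (is.null(prob)) NA_real_ else rank_auc(truth, prob)
  tibble::tibble(
    accuracy = (tp + tn) / length(truth),
    precision = precision, recall = recall, f1 = f1, auc = auc,
    tp = tp, tn = tn, fp = fp, fn = fn, n = length(truth)
  )
}

#' Rank-statistic ROC-AUC
#'
#' The probability that a random positive outranks a random negative
#' (Wilcoxon--Mann--Whitney), with ties counted as half.
#'
#' @inheritParams score_predictions
#' @return AUC in \[0, 1\], or `NA` when only one class is present.
#' @export
rank_auc <- function(truth, prob) {
  n1 <- sum(truth == 1)
  n0 <- sum(truth == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(prob)
  (sum(r[truth == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' @inheritParams score_predictions
#' @return A tibble `threshold, fpr, tpr` sweeping the observed probability
#'   values from high to low.
#' @export
roc_points <- function(truth, prob) {
  ths <- c(Inf, sort(unique(prob), decreasing = TRUE), -Inf)
  purrr::map_dfr(ths, function(th) {
    pred <- as.integer(prob >= th)
    tibble::tibble(
      threshold = th,
      fpr = if (sum(truth == 0) == 0) NA_real_ else
        sum(pred == 1 & truth == 0) / sum(truth == 0),
      tpr = if (sum(truth == 1) == 0) NA_real_ else
        sum(pred == 1 & truth == 1) / sum(truth == 1)
    )
  })
}

#' Paired comparison of two experiment reports
#'
#' Two-sided Wilcoxon matched-pairs signed-rank test on per-fold scores of
#' two experiments run on identical fold assignments (e.g. ensemble vs a
#' single learner, or two atlases). All-zero differences — identical reports
#' — return `p = 1` by convention.
#'
#' @param report_a,report_b `gm_experiment` objects (see [run_experiment()])
#'   or tibbles with a per-fold score column.
#' @param metric Score column to compare (default `"f1"`).
#' @return A tibble `metric, statistic, p, n_folds`.
#' @export
compare_reports <- function(report_a, report_b, metric = "f1") {
  a <- fold_scores(report_a, metric)
  b <- fold_scores(report_b, metric)
  if (length(a) != length(b)) abort("compare_reports: unequal fold counts")
  d <- a - b
  if (all(d == 0, na.rm = TRUE)) {
    return(tibble::tibble(metric = metric, statistic = NA_real_, p = 1,
                          n_folds = length(a)))
  }
  # exact null distribution when fold counts are small and untied
  wt <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE))
  tibble::tibble(metric = metric, statistic = unname(wt$statistic),
                 p = wt$p.value, n_folds = length(a))
}

fold_scores <- function(report, metric) {
  tbl <- if (inherits(report, "gm_experiment")) report$folds else report
  if (!metric %in% names(tbl)) {
    abort(paste0("compare_reports: no per-fold column `", metric, "`"))
  }
  tbl[[metric]]
}
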