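#' Confusion counts from truth and predicted labels
#'
#' @param truth binary vector of true labels (0/1).
#' @param pred binary vector of predicted labels (0/1).
#' @return Named integer vector `c(TP, FN, FP, TN)`.
#' @export
confusion_counts <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  c(TP = sum(truth == 1L & pred == 1L),
    FN = sum(truth == 1L & pred == 0L),
    FP = sum(truth == 0L & pred == 1L),
    TN = sum(truth == 0L & pred == 0L))
}

#' Sensitivity, specificity, accuracy and MCC from confusion counts
#'
#' `Sn = TP/(TP+FN)`, `Sp = TN/(TN+FP)` and `ACC = (TP+TN)/total`, all as
#' percentages; `MCC = (TP*TN - FP*FN) / sqrt((TP+FN)(TP+FP)(TN+FN)(TN+FP))`,
#' defined as 0 when any factor of the denominator is 0.
#'
#' @param counts named vector or list with `TP`, `FN`, `FP`, `TN`.
#' @return Named numeric vector `c(Sn, Sp, ACC, MCC)`; Sn/Sp/ACC on the
#'   percentage scale, full precision (round only for display).
#' @export
compute_metrics <- function(counts) {
  tp <- as.numeric(counts[["TP"]]); fn <- as.numeric(counts[["FN"]])
  fp <- as.numeric(counts[["FP"]]); tn <- as.numeric(counts[["TN"]])
  if (any(c(tp, fn, fp, tn) < 0)) stop("negative confusion counts")
  if (tp + fn == 0 || tn + fp == 0)
    stop("both classes must be present (TP+FN > 0 and TN+FP > 0)")
  denom <- (tp + fn) * (tp + fp) * (tn + fn) * (tn + fp)
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / sqrt(denom)
  c(Sn = 100 * tp / (tp + fn),
    Sp = 100 * tn / (tn + fp),
    ACC = 100 * (tp + tn) / (tp + fn + fp + tn),
    MCC = mcc)
}

#' ROC curve and AUC
#'
#' The ROC is traced over all distinct score thresholds (predict positive
#' when score >= threshold), starts at (0,0) and ends at (1,1); AUC is the
#' trapezoidal area, equal to the fraction of (positive, negative) pairs
#' ranked correctly with half credit for ties.
#'
#' @param labels binary truth vector (0/1), both classes present.
#' @param scores numeric scores, larger = more positive.
#' @return List with `roc` (data frame `fpr`, `tpr`) and `auc`.
#' @export
roc_auc <- function(labels, scores) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) stop("both classes required for ROC")
  if (any(!is.finite(scores))) stop("scores must be finite")
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]; sc <- scores[ord]
  # cumulative counts at each distinct threshold
  keep <- c(sc[-1] != sc[-length(sc)], TRUE)
  tp <- cumsum(lab == 1L)[keep]
  fp <- cumsum(lab == 0L)[keep]
  P <- sum(labels == 1L); N <- sum(labels == 0L)
  roc <- data.frame(fpr = c(0, fp / N), tpr = c(0, tp / P))
  auc <- sum(diff(roc$fpr) * (roc$tpr[-1] + roc$tpr[-nrow(roc)]) / 2)
  list(roc = roc, auc = auc)
}

eval_report <- function(truth, pred, scores) {
  counts <- confusion_counts(truth, pred)
  r <- roc_auc(truth, scores)
  structure(list(counts = counts, metrics = compute_metrics(counts),
                 roc = r$roc, auc = r$auc),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  m <- round(x$metrics, 3)
  cat("<eval_report> TP=", x$counts[["TP"]], " FN=", x$counts[["FN"]],
      " FP=", x$counts[["FP"]], " TN=", x$counts[["TN"]],
      "\n  Sn=", m[["Sn"]], "% Sp=", m[["Sp"]], "% ACC=", m[["ACC"]],
      "% MCC=", m[["MCC"]], " AUC=", round(x$auc, 4), "\n", sep = "")
  invisible(x)
}

#' Stratified k-fold cross-validation of the SVM
#'
#' Trains one SVM per fold and pools the held-out predictions into a single
#' confusion table (so `TP+FN` equals the full positive count); per-fold
#' metrics are reported alongside. ROC/AUC are computed on the pooled
#' held-out decision scores.
#'
#' @param x labeled feature matrix.
#' @param y binary labels; defaults to the matrix `label` attribute.
#' @param folds number of folds (default 10).
#' @param C,gamma SVM hyperparameters (`gamma` defaults to `1/ncol(x)`).
#' @param probability calibrate per-fold probabilities (slower); otherwise
#'   labels come from the decision-value sign, equivalent to the 0.5
#'   probability threshold up to calibration.
#' @param seed fold seed.
#' @return List: `pooled` ([eval_report]), `per_fold` (data frame),
#'   `predictions` (per-sample fold, score, label).
#' @export
kfold_cv <- function(x, y = matrix_labels(x), folds = 10L, C = 1,
                     gamma = 1 / ncol(x), probability = FALSE, seed = 42L) {
  y <- check_xy(x, y)
  fold <- make_folds(y, folds, seed)
  score <- numeric(length(y)); pred <- integer(length(y))
  for (f in seq_len(folds)) {
    tr <- fold != f
    model <- svm_train(x[tr, , drop = FALSE], y[tr], C = C, gamma = gamma,
                       probability = probability, seed = seed)
    p <- predict(model, x[!tr, , drop = FALSE])
    if (probability) {
      score[!tr] <- p$probability
      pred[!tr] <- p$label
    } else {
      score[!tr] <- p$decision
      pred[!tr] <- as.integer(p$decision >= 0)
    }
  }
  per_fold <- do.call(rbind, lapply(seq_len(folds), function(f) {
    i <- fold == f
    m <- compute_metrics(confusion_counts(y[i], pred[i]))
    data.frame(fold = f, t(m))
  }))
  list(pooled = eval_report(y, pred, score), per_fold = per_fold,
       predictions = data.frame(fold = fold, score = score, pred = pred,
                                truth = y))
}
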