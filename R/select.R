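# Backward elimination over the boosting-derived importance ranking.
# During elimination the SVM runs with fixed parameters (C = 1,
# gamma = 1/|subset|) and labels from the decision-value sign; the full grid
# search is reserved for the final subset. Pairwise squared distances are
# maintained incrementally across elimination steps (removing a dimension
# subtracts its rank-one contribution), which makes the ~300-step trace
# cheap.

# Shared inner evaluation: given per-fold squared-distance blocks and labels,
# fit/score one subset. Returns pooled counts, metrics, and fold-mean AUC.
eval_subset_kernels <- function(d2_list, y, fold, gamma, C) {
  nfold <- length(d2_list)
  pred <- integer(length(y)); score <- numeric(length(y))
  auc <- numeric(nfold)
  for (f in seq_len(nfold)) {
    tr <- fold != f
    Ktr <- rbf_kernel(d2_list[[f]]$tr, gamma)
    fit <- svm_fit_kernel(Ktr, y[tr], C)
    dec <- as.numeric(rbf_kernel(d2_list[[f]]$te, gamma) %*% fit$coef) + fit$b
    pred[!tr] <- as.integer(dec >= 0)
    score[!tr] <- dec
    auc[f] <- roc_auc(y[!tr], dec)$auc
  }
  counts <- confusion_counts(y, pred)
  list(counts = counts, metrics = compute_metrics(counts), auc = mean(auc))
}

#' Cross-validated performance of one feature subset
#'
#' Scores a dimension subset by stratified k-fold cross-validation with an
#' RBF SVM at fixed parameters (`C`, `gamma = 1/|subset|` unless given).
#' Confusion counts are pooled over folds; AUC is the mean of per-fold AUCs
#' of the decision values.
#'
#' @param x labeled feature matrix.
#' @param y binary labels; defaults to the matrix `label` attribute.
#' @param subset integer vector of retained dimension (column) indices.
#' @param cv_folds number of folds (default 10).
#' @param seed fold seed (same seed = same folds, comparable across subsets).
#' @param C SVM box penalty (default 1).
#' @param gamma RBF width; default `1/length(subset)`.
#' @return Named numeric vector `c(Sn, Sp, ACC, MCC, AUC)`.
#' @export
evaluate_subset <- function(x, y = matrix_labels(x), subset,
                            cv_folds = 10L, seed = 42L, C = 1,
                            gamma = 1 / length(subset)) {
  y <- check_xy(x, y)
  subset <- as.integer(subset)
  if (length(subset) == 0L) stop("subset must be non-empty")
  if (any(subset < 1L | subset > ncol(x))) stop("subset index out of range")
  fold <- make_folds(y, cv_folds, seed)
  xs <- x[, subset, drop = FALSE]
  d2_list <- lapply(seq_len(cv_folds), function(f) {
    tr <- fold != f
    list(tr = sqdist(xs[tr, , drop = FALSE]),
         te = sqdist(xs[!tr, , drop = FALSE], xs[tr, , drop = FALSE]))
  })
  r <- eval_subset_kernels(d2_list, y, fold, gamma, C)
  c(r$metrics, AUC = r$auc)
}

#' Backward elimination over an importance ranking
#'
#' Starting from the full ranked feature space, the lowest-ranked dimensions
#' are dropped `stride` at a time; each retained prefix of the ranking is
#' scored by [evaluate_subset()]'s procedure on folds fixed once by `seed`.
#' The best subset maximizes pooled CV accuracy, with ties broken by higher
#' MCC and then by the smaller subset.
#'
#' @param x labeled feature matrix.
#' @param y binary labels; defaults to the matrix `label` attribute.
#' @param ranking an `importance_ranking` from [rank_features()] covering
#'   all columns of `x`.
#' @param cv_folds folds for every subset evaluation (default 10).
#' @param min_size smallest subset size to consider (default 1).
#' @param stride dimensions removed per step (default 1; larger values give
#'   a coarser, faster trace).
#' @param seed fold seed.
#' @param C SVM box penalty used throughout the elimination (default 1;
#'   `gamma` is always `1/|subset|`).
#' @return A `selection_result`: `best_subset` (dimension indices, a prefix
#'   of the ranking), `trace` (one row per step: size, Sn, Sp, ACC, MCC,
#'   AUC), `criterion`, and the evaluation settings.
#' @export
backward_eliminate <- function(x, y = matrix_labels(x), ranking,
                               cv_folds = 10L, min_size = 1L, stride = 1L,
                               seed = 42L, C = 1) {
  y <- check_xy(x, y)
  if (!inherits(ranking, "importance_ranking")) stop("not an importance_ranking")
  p <- ncol(x)
  if (length(ranking$order) != p) stop("ranking does not cover the matrix (",
                                       length(ranking$order), " vs ", p, ")")
  stopifnot(min_size >= 1L, min_size < p, stride >= 1L)
  fold <- make_folds(y, cv_folds, seed)
  xr <- x[, ranking$order, drop = FALSE]  # columns in rank order

  # full-space squared distances per fold; shrink incrementally
  d2_list <- lapply(seq_len(cv_folds), function(f) {
    tr <- fold != f
    list(tr = sqdist(xr[tr, , drop = FALSE]),
         te = sqdist(xr[!tr, , drop = FALSE], xr[tr, , drop = FALSE]))
  })

  sizes <- seq(p, min_size, by = -stride)
  trace <- vector("list", length(sizes))
  size_prev <- p
  for (s in seq_along(sizes)) {
    size <- sizes[s]
    if (size < size_prev) {
      drop_cols <- (size + 1L):size_prev
      for (f in seq_len(cv_folds)) {
        tr <- fold != f
        for (d in drop_cols) {
          v <- xr[, d]
          dv_tr <- outer(v[tr], v[tr], "-")
          dv_te <- outer(v[!tr], v[tr], "-")
          d2_list[[f]]$tr <- pmax(d2_list[[f]]$tr - dv_tr * dv_tr, 0)
          d2_list[[f]]$te <- pmax(d2_list[[f]]$te - dv_te * dv_te, 0)
        }
      }
    }
    r <- eval_subset_kernels(d2_list, y, fold, gamma = 1 / size, C = C)
    trace[[s]] <- data.frame(size = size, t(r$metrics), AUC = r$auc)
    size_prev <- size
  }
  trace <- do.call(rbind, trace)
  best_row <- order(-trace$ACC, -trace$MCC, trace$size)[1L]
  best_size <- trace$size[best_row]
  structure(list(best_subset = ranking$order[seq_len(best_size)],
                 best_size = best_size,
                 trace = trace, criterion = "ACC (ties: MCC, smaller subset)",
                 cv_folds = cv_folds, seed = seed, C = C,
                 gamma_rule = "1/|subset|", stride = stride),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  b <- x$trace[x$trace$size == x$best_size, ]
  cat("<selection_result> best subset: ", x$best_size, " dimensions (ACC=",
      round(b$ACC, 2), "%, MCC=", round(b$MCC, 3), "); trace of ",
      nrow(x$trace), " steps\n", sep = "")
  invisible(x)
}

#' Write a selection result to disk
#'
#' Writes `<prefix>trace.tsv` (the per-step CV trace) and
#' `<prefix>retained.txt` (one retained dimension per line, `D<i>`).
#'
#' @param sel a `selection_result`.
#' @param prefix output path prefix (e.g. `"selection/"`).
#' @return `prefix`, invisibly.
#' @export
write_selection <- function(sel, prefix) {
  utils::write.table(sel$trace, paste0(prefix, "trace.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(paste0("D", sel$best_subset), paste0(prefix, "retained.txt"))
  invisible(prefix)
}
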