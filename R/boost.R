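#' Boosting configuration for the importance ranker
#'
#' Hyperparameters of the gradient-boosted tree ensemble used only to score
#' feature importance (the predictor itself is the SVM). Defaults follow the
#' common boosted-tree library defaults: 100 rounds, depth 6, learning rate
#' 0.3, L2 regularization 1; histogram construction is single-threaded and
#' deterministic, so a fixed seed yields identical scores.
#'
#' @param nrounds number of boosting rounds.
#' @param max_depth maximum tree depth.
#' @param eta learning rate.
#' @param lambda L2 regularization on leaf weights.
#' @param min_child_weight minimum hessian sum per child.
#' @param nbins number of histogram bins per feature.
#' @return A `boost_config` list.
#' @export
boost_config <- function(nrounds = 100L, max_depth = 6L, eta = 0.3,
                         lambda = 1, min_child_weight = 1, nbins = 256L) {
  structure(list(nrounds = as.integer(nrounds), max_depth = as.integer(max_depth),
                 eta = eta, lambda = lambda, min_child_weight = min_child_weight,
                 nbins = as.integer(nbins)),
            class = "boost_config")
}

#' Train the boosted-tree importance ranker
#'
#' Fits a gradient-boosted tree ensemble (binary logistic loss) on the full
#' labeled feature matrix and records, per dimension, the split statistics
#' from which importance scores are derived: `weight` (number of times the
#' dimension is chosen as a split variable), `gain` (total split gain) and
#' `cover` (total hessian of split nodes). Tree construction is
#' deterministic, so repeated runs give identical scores.
#'
#' @param x numeric feature matrix (samples x dimensions), e.g. from
#'   [encode_all()].
#' @param y binary labels (0/1); defaults to the matrix `label` attribute.
#' @param config a [boost_config].
#' @param seed RNG seed (kept for interface stability; the ensemble itself
#'   uses no randomness).
#' @return A `meth4c_ranker` object.
#' @export
train_ranker <- function(x, y = matrix_labels(x), config = boost_config(),
                         seed = 42L) {
  y <- check_xy(x, y)
  fit <- gbtree_train(x, as.numeric(y), config$nrounds, config$max_depth,
                      config$eta, config$lambda, config$min_child_weight,
                      config$nbins)
  structure(list(importance = list(weight = fit$weight, gain = fit$gain,
                                   cover = fit$cover),
                 fitted = fit$fitted, config = config, seed = seed,
                 n_features = ncol(x),
                 feature_names = colnames(x)),
            class = "meth4c_ranker")
}

#' Rank feature dimensions by importance
#'
#' Orders all dimensions from highest to lowest importance score; ties are
#' broken by ascending dimension index, and zero-score dimensions (never used
#' in a split) come after all positive-score dimensions.
#'
#' @param ranker a fitted `meth4c_ranker` from [train_ranker()].
#' @param type importance flavour: `"weight"` (default, split counts),
#'   `"gain"` or `"cover"`.
#' @return An `importance_ranking`: list with `scores` (per-dimension),
#'   `order` (permutation, best first) and `importance_type`.
#' @export
rank_features <- function(ranker, type = c("weight", "gain", "cover")) {
  if (!inherits(ranker, "meth4c_ranker")) stop("not a fitted ranker")
  type <- match.arg(type)
  scores <- ranker$importance[[type]]
  ord <- order(-scores, seq_along(scores))
  structure(list(scores = scores, order = ord, importance_type = type,
                 feature_names = ranker$feature_names),
            class = "importance_ranking")
}

#' @export
print.importance_ranking <- function(x, ...) {
  cat("<importance_ranking> ", length(x$scores), " dimensions by '",
      x$importance_type, "'; top 5: ",
      paste0("D", x$order[1:5], " (", signif(x$scores[x$order[1:5]], 3), ")",
             collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Write an importance ranking to TSV
#'
#' Two columns (`dimension`, `score`), one row per dimension, sorted from
#' highest to lowest rank.
#'
#' @param ranking an `importance_ranking`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranking, path) {
  df <- data.frame(dimension = paste0("D", ranking$order),
                   score = ranking$scores[ranking$order])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
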