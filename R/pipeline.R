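#' Full-pipeline configuration
#'
#' Bundles the settings of every stage of the predictor: encoding, boosted
#' importance ranking, backward elimination, hyperparameter grid search and
#' the final probability-calibrated SVM.
#'
#' @param encoder an [encoder_config].
#' @param boost a [boost_config].
#' @param select_folds,select_min_size,select_stride backward-elimination
#'   settings (see [backward_eliminate()]).
#' @param grid hyperparameter candidates from [svm_grid()].
#' @param grid_folds folds for the final grid search.
#' @param threshold probability threshold for the positive call.
#' @param run_selection set `FALSE` to skip ranking/elimination and train on
#'   the full feature space.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(encoder = encoder_config(), boost = boost_config(),
                            select_folds = 10L, select_min_size = 1L,
                            select_stride = 1L, grid = svm_grid(),
                            grid_folds = 10L, threshold = 0.5,
                            run_selection = TRUE) {
  structure(list(encoder = encoder, boost = boost,
                 select_folds = as.integer(select_folds),
                 select_min_size = as.integer(select_min_size),
                 select_stride = as.integer(select_stride),
                 grid = grid, grid_folds = as.integer(grid_folds),
                 threshold = threshold, run_selection = run_selection),
            class = "pipeline_config")
}

# Fit the whole pipeline on an encoded, labeled matrix. Internal: shared by
# independent_test() and the CLI `train` command.
fit_pipeline <- function(x, y, config, seed) {
  ranking <- NULL; selection <- NULL
  subset <- seq_len(ncol(x))
  if (config$run_selection) {
    ranker <- train_ranker(x, y, config$boost, seed = seed)
    ranking <- rank_features(ranker)
    selection <- backward_eliminate(x, y, ranking,
                                    cv_folds = config$select_folds,
                                    min_size = config$select_min_size,
                                    stride = config$select_stride,
                                    seed = seed)
    subset <- selection$best_subset
  }
  xs <- x[, subset, drop = FALSE]
  cfg <- grid_search(xs, y, grid = config$grid, cv_folds = config$grid_folds,
                     seed = seed)
  model <- svm_train(xs, y, C = cfg$C, gamma = cfg$gamma, probability = TRUE,
                     seed = seed, threshold = config$threshold)
  list(model = model, svm_config = cfg, ranking = ranking,
       selection = selection, subset = subset)
}

#' Independent test of the full pipeline
#'
#' Fits every stage — encoding, importance ranking, backward elimination,
#' grid search, SVM training — on the training windows only, then evaluates
#' once on the held-out test windows. Overlapping sample ids between the two
#' sets are rejected as leakage.
#'
#' @param train,test labeled [sample_set]s with disjoint ids.
#' @param config a [pipeline_config].
#' @param seed seed controlling fold assignments throughout.
#' @return List: `report` (an eval_report on the test set), `model`,
#'   `svm_config`, `ranking`, `selection`, `subset`, and the per-sample test
#'   `predictions`.
#' @export
independent_test <- function(train, test, config = pipeline_config(),
                             seed = 42L) {
  stopifnot(inherits(train, "sample_set"), inherits(test, "sample_set"))
  overlap <- intersect(train$id, test$id)
  if (length(overlap) > 0L)
    stop("leakage: ", length(overlap), " sample id(s) appear in both train ",
         "and test (e.g. '", overlap[1L], "')")
  xtr <- encode_all(train, config$encoder)
  xte <- encode_all(test, config$encoder)
  fit <- fit_pipeline(xtr, matrix_labels(xtr), config, seed)
  pred <- predict(fit$model, xte[, fit$subset, drop = FALSE])
  ytest <- matrix_labels(xte)
  list(report = eval_report(ytest, pred$label, pred$probability),
       model = fit$model, svm_config = fit$svm_config,
       ranking = fit$ranking, selection = fit$selection,
       subset = fit$subset, predictions = cbind(pred, truth = ytest))
}
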