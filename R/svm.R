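# RBF-kernel support vector classification. The quadratic program is solved
# by the SMO routine in src/smo.cpp on a precomputed kernel matrix;
# probability outputs come from a sigmoid fit (Platt scaling) on
# cross-validated decision values.

#' Hyperparameter grid for the RBF SVM
#'
#' Default exponent grids: `C` in `2^-5 .. 2^10` and `gamma` in
#' `2^-15 .. 2^2`, both in multiplicative steps of 2 (16 x 18 candidates).
#'
#' @param C candidate box penalties.
#' @param gamma candidate RBF widths.
#' @return A list with components `C` and `gamma`.
#' @export
svm_grid <- function(C = 2^seq(-5L, 10L), gamma = 2^seq(-15L, 2L)) {
  stopifnot(length(C) > 0L, length(gamma) > 0L, all(C > 0), all(gamma > 0))
  list(C = sort(C), gamma = sort(gamma))
}

# Fit on a precomputed kernel; y01 in {0,1}. Returns coef (alpha_i * y_i), b.
svm_fit_kernel <- function(K, y01, C, eps = 1e-3, max_iter = 200000L) {
  ypm <- ifelse(y01 == 1L, 1L, -1L)
  fit <- smo_solve(K, as.integer(ypm), C, eps, as.integer(max_iter))
  fit
}

# Platt scaling: fit P(y=1|f) = 1 / (1 + exp(A f + B)) by a damped Newton
# iteration on the regularized targets (Lin, Lin & Weng 2007).
platt_fit <- function(f, y01) {
  prior1 <- sum(y01 == 1L); prior0 <- sum(y01 == 0L)
  hi <- (prior1 + 1) / (prior1 + 2); lo <- 1 / (prior0 + 2)
  t <- ifelse(y01 == 1L, hi, lo)
  A <- 0; B <- log((prior0 + 1) / (prior1 + 1))
  obj_fun <- function(A, B) {
    fApB <- A * f + B
    sum(ifelse(fApB >= 0,
               t * fApB + log1p(exp(-fApB)),
               (t - 1) * fApB + log1p(exp(fApB))))
  }
  fval <- obj_fun(A, B)
  sigma <- 1e-12
  for (it in 1:100) {
    fApB <- A * f + B
    p <- ifelse(fApB >= 0, exp(-fApB) / (1 + exp(-fApB)), 1 / (1 + exp(fApB)))
    q <- 1 - p
    d1 <- t - p
    d2 <- p * q
    g1 <- sum(f * d1); g2 <- sum(d1)
    if (abs(g1) < 1e-5 && abs(g2) < 1e-5) break
    h11 <- sum(f * f * d2) + sigma
    h22 <- sum(d2) + sigma
    h21 <- sum(f * d2)
    det <- h11 * h22 - h21 * h21
    dA <- -(h22 * g1 - h21 * g2) / det
    dB <- -(-h21 * g1 + h11 * g2) / det
    gd <- g1 * dA + g2 * dB
    step <- 1
    repeat {  # backtracking line search
      newA <- A + step * dA; newB <- B + step * dB
      newf <- obj_fun(newA, newB)
      if (newf < fval + 1e-4 * step * gd) {
        A <- newA; B <- newB; fval <- newf; break
      }
      step <- step / 2
      if (step < 1e-10) return(list(A = A, B = B))
    }
  }
  list(A = A, B = B)
}

#' Train an RBF-kernel SVM classifier
#'
#' @param x numeric feature matrix (samples x dimensions); column names are
#'   recorded and enforced at prediction time.
#' @param y binary labels (0/1); defaults to the matrix `label` attribute.
#' @param C box penalty.
#' @param gamma RBF width; default `1/ncol(x)`.
#' @param probability fit a sigmoid on internally cross-validated decision
#'   values so that [predict.meth4c_svm()] can return calibrated
#'   probabilities (default `TRUE`).
#' @param calib_folds internal folds for the calibration decision values.
#' @param seed seed fixing the internal calibration folds.
#' @param threshold probability threshold for the positive call, default 0.5
#'   (a probability of exactly 0.5 is called positive).
#' @return A `meth4c_svm` model.
#' @export
svm_train <- function(x, y = matrix_labels(x), C = 1, gamma = 1 / ncol(x),
                      probability = TRUE, calib_folds = 5L, seed = 42L,
                      threshold = 0.5) {
  y <- check_xy(x, y)
  d2 <- sqdist(x)
  K <- rbf_kernel(d2, gamma)
  fit <- svm_fit_kernel(K, y, C)
  platt <- NULL
  if (probability) {
    # out-of-fold decision values to avoid optimistic calibration
    fold <- make_folds(y, calib_folds, seed)
    dec <- numeric(length(y))
    for (f in seq_len(calib_folds)) {
      tr <- fold != f
      Kf <- rbf_kernel(d2[tr, tr, drop = FALSE], gamma)
      ff <- svm_fit_kernel(Kf, y[tr], C)
      Kx <- rbf_kernel(d2[!tr, tr, drop = FALSE], gamma)
      dec[!tr] <- as.numeric(Kx %*% ff$coef) + ff$b
    }
    platt <- platt_fit(dec, y)
  }
  sv <- which(abs(fit$coef) > 1e-12)
  structure(list(C = C, gamma = gamma, kernel = "RBF", threshold = threshold,
                 sv_x = x[sv, , drop = FALSE], sv_coef = fit$coef[sv],
                 b = fit$b, platt = platt, dims = colnames(x),
                 n_features = ncol(x), seed = seed,
                 fingerprint = c(n = nrow(x), pos = sum(y == 1L))),
            class = "meth4c_svm")
}

svm_decision <- function(model, newdata) {
  K <- rbf_kernel(sqdist(newdata, model$sv_x), model$gamma)
  as.numeric(K %*% model$sv_coef) + model$b
}

#' Predict 4mC probability and label
#'
#' Labels are positive when the probability of the positive class is greater
#' than or equal to the threshold (boundary assigned to positive). Without
#' probability calibration, the raw decision value is mapped through a unit
#' sigmoid, which preserves the decision-boundary sign.
#'
#' @param object a `meth4c_svm` model.
#' @param newdata numeric matrix with exactly the model's feature columns.
#' @param threshold probability threshold; defaults to the model's.
#' @param ... unused.
#' @return A data frame with columns `id`, `probability`, `label`, `decision`.
#' @export
predict.meth4c_svm <- function(object, newdata, threshold = object$threshold, ...) {
  if (!is.matrix(newdata)) newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_features)
    stop("feature mismatch: model expects ", object$n_features,
         " dimensions, got ", ncol(newdata))
  if (!is.null(object$dims) && !is.null(colnames(newdata)) &&
      !identical(colnames(newdata), object$dims))
    stop("feature mismatch: column names differ from the training dimensions")
  dec <- svm_decision(object, newdata)
  prob <- if (!is.null(object$platt))
    1 / (1 + exp(object$platt$A * dec + object$platt$B))
  else 1 / (1 + exp(-dec))
  data.frame(id = rownames(newdata) %||% seq_len(nrow(newdata)),
             probability = prob,
             label = as.integer(prob >= threshold),
             decision = dec, row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Grid search for SVM hyperparameters
#'
#' Evaluates every `(C, gamma)` candidate by stratified cross-validation and
#' returns the pair with the highest pooled CV accuracy; ties are broken by
#' smaller `C`, then smaller `gamma`. Fold assignment is fixed by `seed` and
#' shared across candidates.
#'
#' @param x labeled feature matrix.
#' @param y binary labels (0/1); defaults to the matrix `label` attribute.
#' @param grid candidate set from [svm_grid()].
#' @param cv_folds number of folds (default 10).
#' @param seed fold seed.
#' @return An `svm_config` list: `C`, `gamma`, `kernel`, `threshold`,
#'   `cv_acc`, plus the full candidate table in `$results`.
#' @export
grid_search <- function(x, y = matrix_labels(x), grid = svm_grid(),
                        cv_folds = 10L, seed = 42L) {
  y <- check_xy(x, y)
  fold <- make_folds(y, cv_folds, seed)
  d2 <- sqdist(x)
  res <- expand.grid(C = grid$C, gamma = grid$gamma, KEEP.OUT.ATTRS = FALSE)
  res$acc <- NA_real_
  splits <- lapply(seq_len(cv_folds), function(f) list(tr = fold != f, te = fold == f))
  for (g in grid$gamma) {
    Ks <- lapply(splits, function(s) list(
      tr = rbf_kernel(d2[s$tr, s$tr, drop = FALSE], g),
      te = rbf_kernel(d2[s$te, s$tr, drop = FALSE], g)))
    for (C in grid$C) {
      correct <- 0L
      for (f in seq_len(cv_folds)) {
        s <- splits[[f]]
        fit <- svm_fit_kernel(Ks[[f]]$tr, y[s$tr], C)
        dec <- as.numeric(Ks[[f]]$te %*% fit$coef) + fit$b
        correct <- correct + sum((dec >= 0) == (y[s$te] == 1L))
      }
      res$acc[res$C == C & res$gamma == g] <- correct / length(y)
    }
  }
  best <- res[order(-res$acc, res$C, res$gamma), ][1L, ]
  structure(list(C = best$C, gamma = best$gamma, kernel = "RBF",
                 threshold = 0.5, cv_acc = best$acc, results = res),
            class = "svm_config")
}
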