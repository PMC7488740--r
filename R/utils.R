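# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Stratified fold assignment: within each class, samples are permuted under
# `seed` and dealt round-robin into `k` folds. Returns an integer vector of
# fold ids (1..k) aligned with `y`.
make_folds <- function(y, k, seed) {
  stopifnot(k >= 2L)
  fold <- integer(length(y))
  with_seed(seed, {
    for (cls in sort(unique(y))) {
      idx <- which(y == cls)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  tab <- table(fold, y)
  if (any(tab == 0L))
    stop("fold ", rownames(tab)[which(rowSums(tab == 0L) > 0L)[1L]],
         " does not contain both classes; reduce the number of folds")
  fold
}

# Pairwise squared Euclidean distances; `b` may be NULL for the symmetric case.
sqdist <- function(a, b = NULL) {
  if (is.null(b)) b <- a
  an <- rowSums(a * a); bn <- rowSums(b * b)
  d <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  d[d < 0] <- 0
  d
}

rbf_kernel <- function(d2, gamma) exp(-gamma * d2)

check_xy <- function(x, y) {
  stopifnot(is.matrix(x), nrow(x) == length(y))
  if (anyNA(x)) stop("feature matrix contains missing values")
  if (nrow(x) == 0L) stop("empty feature matrix")
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L))) stop("labels must be binary 0/1")
  if (length(unique(y)) < 2L) stop("training data contain a single class")
  if (min(table(y)) < 2L) stop("need at least 2 samples per class")
  y
}

# labels attached to an encoded matrix, with validation
matrix_labels <- function(x) {
  y <- attr(x, "label")
  if (is.null(y)) stop("feature matrix has no 'label' attribute")
  y
}
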