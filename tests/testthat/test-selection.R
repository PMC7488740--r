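test_that("evaluate_subset is exact on separable data and deterministic", {
  x <- generate_feature_table(100, 2, 8, effect = 8, seed = 11)
  m1 <- evaluate_subset(x, subset = 1:2, cv_folds = 5, seed = 1)
  expect_equal(m1[["ACC"]], 100)
  expect_equal(m1[["MCC"]], 1)
  m2 <- evaluate_subset(x, subset = 1:2, cv_folds = 5, seed = 1)
  expect_identical(m1, m2)
  expect_error(evaluate_subset(x, subset = integer(0)), "non-empty")
  expect_error(evaluate_subset(x, subset = 99), "out of range")
})

test_that("label-shuffled data score at chance on a fixed subset", {
  x <- generate_feature_table(400, 0, 20, effect = 0, seed = 12)
  m <- evaluate_subset(x, subset = 1:20, cv_folds = 10, seed = 12)
  expect_gt(m[["ACC"]], 45)
  expect_lt(m[["ACC"]], 55)
})

test_that("backward elimination walks the full trace and returns a prefix", {
  x <- generate_feature_table(80, 2, 1, effect = 3, seed = 13)
  rk <- rank_features(train_ranker(x))
  sel <- backward_eliminate(x, ranking = rk, cv_folds = 5, min_size = 1,
                            seed = 13)
  expect_equal(nrow(sel$trace), 3L)            # sizes 3, 2, 1
  expect_equal(sel$trace$size, c(3L, 2L, 1L))
  expect_equal(sel$best_subset, rk$order[seq_len(sel$best_size)])
  # argmax construction: best is at least as good as the full space
  expect_gte(sel$trace$ACC[sel$trace$size == sel$best_size],
             sel$trace$ACC[1])
})

test_that("exact criterion ties go to the smaller subset", {
  # duplicated informative column: with gamma = 1/|subset| the size-2 and
  # size-1 kernels are identical, so the trace ties exactly and the smaller
  # subset must win
  x0 <- generate_feature_table(60, 1, 0, effect = 6, seed = 14)
  x <- cbind(x0, x0); colnames(x) <- c("D1", "D2")
  attr(x, "label") <- attr(x0, "label")
  rk <- structure(list(scores = c(2, 1), order = c(1L, 2L),
                       importance_type = "weight"),
                  class = "importance_ranking")
  sel <- backward_eliminate(x, attr(x, "label"), rk, cv_folds = 5, seed = 14)
  expect_equal(sel$trace$ACC[1], sel$trace$ACC[2])
  expect_equal(sel$best_size, 1L)
})

test_that("the incremental trace agrees with direct subset evaluation", {
  x <- generate_feature_table(120, 4, 16, effect = 1.5, seed = 15)
  rk <- rank_features(train_ranker(x))
  sel <- backward_eliminate(x, ranking = rk, cv_folds = 5, seed = 7)
  for (sz in c(20L, 10L, 3L)) {
    direct <- evaluate_subset(x, subset = rk$order[1:sz], cv_folds = 5,
                              seed = 7)
    row <- sel$trace[sel$trace$size == sz, ]
    expect_equal(unname(direct[c("Sn", "Sp", "ACC", "MCC")]),
                 unname(unlist(row[c("Sn", "Sp", "ACC", "MCC")])),
                 tolerance = 1e-8)
  }
})

test_that("stride coarsens the trace and selection results serialize", {
  x <- generate_feature_table(60, 2, 8, effect = 2, seed = 16)
  rk <- rank_features(train_ranker(x))
  sel <- backward_eliminate(x, ranking = rk, cv_folds = 5, stride = 3,
                            seed = 16)
  expect_equal(sel$trace$size, seq(10L, 1L, by = -3L))
  dir <- withr::local_tempdir()
  write_selection(sel, file.path(dir, "sel_"))
  expect_equal(readLines(file.path(dir, "sel_retained.txt")),
               paste0("D", sel$best_subset))
  tr <- read.delim(file.path(dir, "sel_trace.tsv"))
  expect_equal(tr$size, sel$trace$size)
})

test_that("mismatched rankings and bad folds are rejected", {
  x <- generate_feature_table(40, 1, 4, effect = 1, seed = 17)
  rk <- structure(list(scores = 1:3, order = 1:3, importance_type = "weight"),
                  class = "importance_ranking")
  expect_error(backward_eliminate(x, ranking = rk), "cover")
  expect_error(evaluate_subset(x, subset = 1:5, cv_folds = 25), "both classes")
})
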