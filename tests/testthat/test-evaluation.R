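# Published cross-validation confusion counts and the metric values printed
# alongside them (six species, proposed-method rows).
published_cv_rows <- data.frame(
  species = c("C.elegans", "D.melanogaster", "A.thaliana", "E.coli",
              "G.subterraneus", "G.pickeringii"),
  TP = c(1319L, 1510L, 1549L, 334L, 757L, 491L),
  FN = c(235L, 259L, 429L, 54L, 148L, 78L),
  FP = c(305L, 297L, 385L, 68L, 129L, 62L),
  TN = c(1249L, 1472L, 1593L, 320L, 776L, 507L),
  Sn = c(84.9, 85.4, 78.3, 86.1, 83.6, 86.3),
  Sp = c(80.4, 83.2, 80.5, 82.5, 85.7, 89.1),
  ACC = c(82.6, 84.3, 79.4, 84.3, 84.7, 87.7),
  MCC = c(0.653, 0.686, 0.589, 0.686, 0.694, 0.754))

test_that("compute_metrics reproduces the published benchmark rows", {
  for (i in seq_len(nrow(published_cv_rows))) {
    r <- published_cv_rows[i, ]
    m <- compute_metrics(c(TP = r$TP, FN = r$FN, FP = r$FP, TN = r$TN))
    expect_lte(abs(round(m[["Sn"]], 1) - r$Sn), 0.05)
    expect_lte(abs(round(m[["Sp"]], 1) - r$Sp), 0.05)
    expect_lte(abs(round(m[["ACC"]], 1) - r$ACC), 0.05)
    expect_lte(abs(round(m[["MCC"]], 3) - r$MCC), 0.05)
  }
})

test_that("compute_metrics handles edge cases by convention", {
  m <- compute_metrics(c(TP = 10, FN = 0, FP = 0, TN = 10))
  expect_equal(unname(m), c(100, 100, 100, 1))
  # zero denominator factor -> MCC 0 (all predicted positive)
  z <- compute_metrics(c(TP = 5, FN = 0, FP = 5, TN = 0))
  expect_equal(z[["MCC"]], 0)
  expect_error(compute_metrics(c(TP = 0, FN = 0, FP = 2, TN = 2)),
               "both classes")
})

test_that("MCC is symmetric under TP/TN and FP/FN swap", {
  set.seed(401)
  for (rep in 1:25) {
    cts <- sample(1:50, 4)
    a <- compute_metrics(c(TP = cts[1], FN = cts[2], FP = cts[3], TN = cts[4]))
    b <- compute_metrics(c(TP = cts[4], FN = cts[3], FP = cts[2], TN = cts[1]))
    expect_equal(a[["MCC"]], b[["MCC"]])
  }
})

test_that("ROC has the right endpoints and AUC matches the pairwise oracle", {
  lab <- c(rep(1L, 5), rep(0L, 5))
  perfect <- roc_auc(lab, c(6:10, 1:5))
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$roc$fpr[1], 0)
  expect_equal(perfect$roc[nrow(perfect$roc), ], data.frame(fpr = 1, tpr = 1),
               ignore_attr = TRUE)
  expect_equal(roc_auc(lab, rep(0.3, 10))$auc, 0.5)
  expect_error(roc_auc(rep(1L, 4), rnorm(4)), "both classes")

  set.seed(402)
  for (rep in 1:50) {
    n <- sample(8:30, 1)
    lab <- rbinom(n, 1, 0.5)
    if (length(unique(lab)) < 2) lab[1:2] <- c(0L, 1L)
    sc <- sample(round(rnorm(n), 1))  # ties likely
    expect_equal(roc_auc(lab, sc)$auc, auc_pairwise_oracle(lab, sc),
                 tolerance = 1e-12)
  }
})

test_that("k-fold CV pools to the full confusion table", {
  x <- generate_feature_table(100, 2, 4, effect = 8, seed = 41)
  y <- attr(x, "label")
  cv <- kfold_cv(x, folds = 5, seed = 3)
  expect_equal(cv$pooled$counts[["TP"]] + cv$pooled$counts[["FN"]],
               sum(y == 1L))
  expect_equal(sum(cv$pooled$counts), length(y))
  expect_equal(cv$pooled$metrics[["ACC"]], 100)  # separable
  expect_equal(nrow(cv$per_fold), 5L)
})

test_that("label-shuffled CV has near-zero MCC", {
  x <- generate_feature_table(400, 0, 10, effect = 0, seed = 42)
  cv <- kfold_cv(x, folds = 10, seed = 4)
  expect_lte(abs(cv$pooled$metrics[["MCC"]]), 0.1)
})

test_that("independent_test rejects id leakage and runs end to end", {
  tr <- generate(30, 30, seed = 43, id_prefix = "a_")
  expect_error(independent_test(tr, tr), "leakage")
  te <- generate(15, 15, seed = 44, id_prefix = "b_")
  cfg <- pipeline_config(select_folds = 5, select_stride = 60,
                         grid = svm_grid(C = c(1, 8), gamma = c(0.01, 0.1)),
                         grid_folds = 5)
  res <- independent_test(tr, te, cfg, seed = 5)
  expect_s3_class(res$report, "eval_report")
  expect_equal(sum(res$report$counts), 30)
  expect_equal(res$subset, res$selection$best_subset)
  # strong default motif, small n: still clearly better than chance
  expect_gt(res$report$metrics[["ACC"]], 70)
})

test_that("a signal-free independent test sits at chance", {
  null_motif <- motif_model(effect_strength = 0)
  tr <- generate(100, 100, motif = null_motif, seed = 45, id_prefix = "tr_")
  te <- generate(50, 50, motif = null_motif, seed = 46, id_prefix = "te_")
  cfg <- pipeline_config(select_folds = 5, select_stride = 30,
                         grid = svm_grid(C = 1, gamma = 2^-8), grid_folds = 5)
  res <- independent_test(tr, te, cfg, seed = 6)
  expect_gte(res$report$metrics[["ACC"]], 43)
  expect_lte(res$report$metrics[["ACC"]], 57)
})
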