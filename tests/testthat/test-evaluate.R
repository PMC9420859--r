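test_that("confusion counts follow the MP-positive convention", {
  cm <- confusion(c(1, 0, 1), c(1, 0, 1))
  expect_equal(unclass(cm)[c("TP", "TN", "FP", "FN")],
               list(TP = 2L, TN = 1L, FP = 0L, FN = 0L))
  cm <- confusion(c(1, 1, 0, 0), c(0, 0, 1, 1))
  expect_equal(c(cm$TP, cm$TN, cm$FP, cm$FN), c(0L, 0L, 2L, 2L))
  cm <- confusion(c(1, 0, 1, 0, 1), c(1, 1, 0, 0, 1))
  expect_equal(c(cm$TP, cm$TN, cm$FP, cm$FN), c(2L, 1L, 1L, 1L))
  expect_error(confusion(c(1, 0), c(1)), "equal length")
})

test_that("metrics implement the printed formulas with zero conventions", {
  m <- class_metrics(list(TP = 9, TN = 8, FP = 1, FN = 2))
  expect_equal(unname(m["ACC"]), 85)
  expect_equal(unname(m["Precision"]), 0.9)
  expect_equal(unname(m["Recall"]), 9 / 11)
  expect_equal(unname(m["F_score"]), 2 * 0.9 * (9 / 11) / (0.9 + 9 / 11))
  z <- class_metrics(list(TP = 0, TN = 5, FP = 0, FN = 0))
  expect_equal(unname(z[c("Precision", "Recall", "F_score")]), c(0, 0, 0))
  p <- class_metrics(list(TP = 4, TN = 6, FP = 0, FN = 0))
  expect_equal(unname(p), c(100, 1, 1, 1))
})

test_that("metrics match independent recomputation on random label vectors", {
  set.seed(71)
  for (i in 1:200) {
    n <- sample(2:60, 1)
    yt <- sample(0:1, n, replace = TRUE)
    yp <- sample(0:1, n, replace = TRUE)
    m <- class_metrics(confusion(yt, yp))
    expect_equal(unname(m["ACC"]), 100 * mean(yt == yp))
    tp <- sum(yt & yp)
    expect_equal(unname(m["Precision"]), if (sum(yp) == 0) 0 else tp / sum(yp))
    expect_equal(unname(m["Recall"]), if (sum(yt) == 0) 0 else tp / sum(yt))
  }
})

test_that("rank AUC equals the all-pairs Mann-Whitney oracle", {
  expect_equal(roc_auc(c(1, 1, 0, 0), c(5, 4, 3, 2)), 1)
  expect_equal(roc_auc(c(1, 0, 1, 0), rep(2, 4)), 0.5)
  expect_equal(roc_auc(c(1, 0, 1, 0), c(0.9, 0.8, 0.3, 0.1)), 0.75)
  expect_error(roc_auc(c(1, 1), c(0.2, 0.3)), "one class")
  set.seed(72)
  for (i in 1:50) {
    n <- sample(4:40, 1)
    y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    s <- sample(round(rnorm(n), 1))  # rounded scores force ties
    expect_equal(roc_auc(y, s), oracle_auc(y, s), tolerance = 1e-12)
  }
})

test_that("rank AUC agrees with the pROC trapezoidal area", {
  set.seed(73)
  y <- c(0, 1, sample(0:1, 48, replace = TRUE))
  s <- rnorm(50)
  expect_equal(roc_auc(y, s),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE, direction = "<"))),
               tolerance = 1e-12)
})

test_that("stratified folds partition samples and balance classes", {
  set.seed(74)
  y <- c(rep(1, 268), rep(0, 162))
  fold <- stratified_folds(y, k = 10, seed = 5)
  expect_equal(sort(unique(fold)), 1:10)
  sizes <- table(fold)
  expect_lte(max(sizes) - min(sizes), 1)
  # per-fold positive count within one of the proportional share
  for (f in 1:10)
    expect_lte(abs(sum(y[fold == f]) - 26.8), 1 + 1e-9)
  # every sample in exactly one test fold, leave-one-out edge case
  y2 <- rep(c(0, 1), 5)
  expect_equal(sort(stratified_folds(y2, k = 10, seed = 1)), 1:10)
  expect_error(stratified_folds(y2, k = 11), "between 2 and n")
})

test_that("cross-validation is seeded, leakage-free and reproducible", {
  recs <- generate_sequences(60, 40, c(40, 80), bias = 0.5, seed = 75)
  X <- encode_features(recs, "svmprot188")
  r1 <- cross_validate(X, recs$label, k = 5, seed = 3, n_members = 5L)
  r2 <- cross_validate(X, recs$label, k = 5, seed = 3, n_members = 5L)
  expect_identical(r1$fold_assignment, r2$fold_assignment)
  expect_identical(r1$folds, r2$folds)
  expect_equal(nrow(r1$folds), 5L)
  expect_equal(sum(r1$folds$n_test), 100L)
  expect_true(all(r1$folds$ACC >= 0 & r1$folds$ACC <= 100))
  expect_gt(unname(r1$mean["ACC"]), 90)  # separable classes
})

test_that("the comparison grid shares folds across cells and nests cross_validate", {
  recs <- generate_sequences(40, 30, c(40, 80), bias = 0.5, seed = 76)
  X <- encode_features(recs, "svmprot188")
  lrn <- builtin_learners()[c("SVM", "KNN")]
  grid <- comparison_grid(list(d188 = X), recs$label, learners = lrn,
                          k = 4, seed = 9, use_lda = TRUE)
  expect_equal(nrow(grid), 2L)
  expect_false(any(grid$skipped))
  # the SVM/LDA-on cell must reproduce cross_validate with a single SVM
  cv <- cross_validate(X, recs$label, k = 4, seed = 9, bagging = FALSE)
  svm_row <- grid[grid$learner == "SVM", ]
  expect_equal(svm_row$ACC, unname(cv$mean["ACC"]), tolerance = 1e-9)
  expect_identical(attr(grid, "fold_assignment"), cv$fold_assignment)
  # an unavailable learner is skipped, not fatal
  fake <- list(FAKE = list(name = "FAKE", available = function() FALSE,
                           fit = NULL, predict = NULL, score = NULL))
  g2 <- comparison_grid(list(d188 = X), recs$label, learners = fake,
                        k = 4, seed = 9, use_lda = TRUE)
  expect_true(g2$skipped)
  expect_true(is.na(g2$ACC))
})

test_that("LDA ablation on linearly structured data keeps accuracy competitive", {
  recs <- generate_sequences(50, 40, c(40, 80), bias = 0.5, seed = 77)
  X <- encode_features(recs, "svmprot188")
  grid <- comparison_grid(list(d188 = X), recs$label,
                          learners = builtin_learners()["SVM"],
                          k = 4, seed = 2, use_lda = c(TRUE, FALSE))
  acc_on <- grid$ACC[grid$lda]
  acc_off <- grid$ACC[!grid$lda]
  expect_gte(acc_on, acc_off - 5)
})
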