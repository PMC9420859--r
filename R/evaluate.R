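#' Confusion counts for binary predictions
#'
#' Class 1 (moonlighting protein) is the positive class: TP = correctly
#' predicted MPs, TN = correctly predicted non-MPs, FP = non-MPs predicted
#' as MPs, FN = MPs predicted as non-MPs.
#'
#' @param y_true,y_pred equal-length binary vectors (0/1).
#' @return list of class `moon_confusion` with integer `TP`, `TN`, `FP`,
#'   `FN`.
#' @export
confusion <- function(y_true, y_pred) {
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have equal length", call. = FALSE)
  stopifnot(all(y_true %in% c(0L, 1L)), all(y_pred %in% c(0L, 1L)))
  structure(list(TP = sum(y_true == 1L & y_pred == 1L),
                 TN = sum(y_true == 0L & y_pred == 0L),
                 FP = sum(y_true == 0L & y_pred == 1L),
                 FN = sum(y_true == 1L & y_pred == 0L)),
            class = "moon_confusion")
}

#' Accuracy, precision, recall and F-score from confusion counts
#'
#' `ACC = (TP + TN) / (TP + TN + FP + FN)` reported in percent;
#' `Precision = TP / (TP + FP)`; `Recall = TP / (TP + FN)`;
#' `F = 2 * Precision * Recall / (Precision + Recall)`. Zero-denominator
#' cases are defined as 0 (no positive predictions gives precision 0, no
#' positives gives recall 0, and F is 0 whenever either is 0).
#'
#' @param cm a `moon_confusion` (or list with TP/TN/FP/FN).
#' @return named numeric vector `ACC` (percent), `Precision`, `Recall`,
#'   `F_score`.
#' @export
class_metrics <- function(cm) {
  n <- cm$TP + cm$TN + cm$FP + cm$FN
  if (n == 0L) stop("empty confusion matrix", call. = FALSE)
  prec <- if (cm$TP + cm$FP == 0L) 0 else cm$TP / (cm$TP + cm$FP)
  rec <- if (cm$TP + cm$FN == 0L) 0 else cm$TP / (cm$TP + cm$FN)
  f <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  c(ACC = 100 * (cm$TP + cm$TN) / n, Precision = prec, Recall = rec, F_score = f)
}

#' Exact ROC AUC (rank / Mann-Whitney form)
#'
#' The area under the ROC curve equals the probability that a random
#' positive outscores a random negative, with ties counted one half:
#' `AUC = [ sum of positive mid-ranks - n_pos (n_pos + 1) / 2 ] /
#' (n_pos * n_neg)`, which is exactly the all-pairs Mann-Whitney
#' statistic.
#'
#' @param y_true binary labels with both classes present.
#' @param scores real-valued scores, higher = more class-1.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(y_true, scores) {
  y_true <- as.integer(y_true)
  stopifnot(length(y_true) == length(scores))
  npos <- sum(y_true == 1L); nneg <- sum(y_true == 0L)
  if (npos == 0L || nneg == 0L)
    stop("AUC is undefined when only one class is present", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[y_true == 1L]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Seeded (stratified) k-fold assignment
#'
#' Assigns each sample to one of `k` test folds. With `stratify = TRUE`
#' (default) samples are shuffled and dealt out within each class, so fold
#' sizes differ by at most one and per-fold class proportions differ from
#' the global ones by at most one sample — the standard protocol for an
#' imbalanced two-class set.
#'
#' @param y binary labels.
#' @param k number of folds (`2 <= k <= n`).
#' @param seed integer seed.
#' @param stratify preserve class proportions per fold.
#' @return integer vector of fold ids in `1..k`.
#' @export
stratified_folds <- function(y, k = 10L, seed = 1L, stratify = TRUE) {
  y <- as.integer(y)
  n <- length(y)
  if (k < 2L || k > n) stop("k must be between 2 and n", call. = FALSE)
  fold <- integer(n)
  with_seed(seed, {
    if (stratify) {
      # deal each class separately; remainders go to the currently
      # smallest folds so total sizes never differ by more than one
      counts <- integer(k)
      for (cls in sort(unique(y))) {
        idx <- sample(which(y == cls))
        n_c <- length(idx)
        sizes <- rep(n_c %/% k, k)
        extra <- n_c %% k
        if (extra > 0) {
          ord <- order(counts, sample.int(k))
          sizes[ord[seq_len(extra)]] <- sizes[ord[seq_len(extra)]] + 1L
        }
        fold[idx] <- rep(seq_len(k), times = sizes)
        counts <- counts + sizes
      }
    } else {
      fold[sample.int(n)] <- rep_len(seq_len(k), n)
    }
  })
  fold
}

#' Stratified k-fold cross-validation of the pipeline
#'
#' Splits the data into `k` seeded stratified folds; for each fold the full
#' pipeline (standardization, LDA projection, bagging-SVM) is fitted on the
#' other k-1 folds only and evaluated on the held-out fold, so no test
#' statistic leaks into training. Per-fold ACC (%), precision, recall,
#' F-score and AUC are reported together with their unweighted means.
#'
#' @param X n x d feature matrix.
#' @param y binary labels (1 = moonlighting).
#' @param k folds (default 10).
#' @param seed seed for the fold assignment and bootstrap substreams.
#' @param stratify stratified folds (default `TRUE`).
#' @param ... pipeline options passed to [fit_pipeline()] (`use_lda`,
#'   `bagging`, `n_members`, `C`, ...).
#' @return object of class `moon_eval`: list with `folds` (per-fold metric
#'   data frame), `mean` (named vector), `fold_assignment`, `config`.
#' @export
cross_validate <- function(X, y, k = 10L, seed = 1L, stratify = TRUE, ...) {
  X <- as.matrix(X)
  y <- as.integer(y)
  stopifnot(nrow(X) == length(y))
  fold <- stratified_folds(y, k = k, seed = seed, stratify = stratify)
  rows <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- fold != f
    if (length(unique(y[tr])) < 2L)
      stop("training split of fold ", f, " lost a class; use a smaller k", call. = FALSE)
    model <- fit_pipeline(X[tr, , drop = FALSE], y[tr], seed = seed + f, ...)
    pred <- predict(model, X[!tr, , drop = FALSE])
    met <- class_metrics(confusion(y[!tr], pred$label))
    auc <- if (length(unique(y[!tr])) == 2L) roc_auc(y[!tr], pred$score) else NA_real_
    rows[[f]] <- data.frame(fold = f, n_test = sum(!tr), t(met), AUC = auc)
  }
  folds <- do.call(rbind, rows)
  mean_row <- colMeans(folds[, c("ACC", "Precision", "Recall", "F_score", "AUC")],
                       na.rm = TRUE)
  structure(list(folds = folds, mean = mean_row, fold_assignment = fold,
                 config = c(list(k = as.integer(k), seed = as.integer(seed),
                                 stratify = stratify), list(...))),
            class = "moon_eval")
}

#' @export
print.moon_eval <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (seed %d)\n", x$config$k, x$config$seed))
  cat(sprintf("mean ACC %.4f%%  Precision %.3f  Recall %.3f  F-score %.3f  AUC %.3f\n",
              x$mean["ACC"], x$mean["Precision"], x$mean["Recall"],
              x$mean["F_score"], x$mean["AUC"]))
  invisible(x)
}

# ---- pluggable comparison learners ------------------------------------

#' Built-in plug-in learners for the comparison grid
#'
#' Off-the-shelf baseline classifiers wrapped in the fit/predict/score
#' contract used by [comparison_grid()]: k-nearest neighbours (`class`),
#' decision tree (`rpart`), multilayer perceptron (`nnet`), random forest
#' (`randomForest`), gradient-boosted trees (`xgboost`) and the linear SVM
#' of this package. Each learner is a list with `name`, `available()`,
#' `fit(X, y, seed)`, `predict(model, X)` (0/1 labels) and
#' `score(model, X)` (class-1 confidence). A learner whose backing package
#' is not installed reports `available() == FALSE` and its grid cells are
#' skipped.
#'
#' @return named list of learner specifications.
#' @export
builtin_learners <- function() {
  list(
    KNN = list(
      name = "KNN", available = function() requireNamespace("class", quietly = TRUE),
      fit = function(X, y, seed) list(X = X, y = y, k = 5L),
      predict = function(m, X) {
        p <- class::knn(m$X, X, factor(m$y, levels = c(0L, 1L)), k = m$k)
        as.integer(as.character(p))
      },
      score = function(m, X) {
        p <- class::knn(m$X, X, factor(m$y, levels = c(0L, 1L)), k = m$k, prob = TRUE)
        pr <- attr(p, "prob")
        ifelse(p == "1", pr, 1 - pr)
      }),
    DT = list(
      name = "DT", available = function() requireNamespace("rpart", quietly = TRUE),
      fit = function(X, y, seed) {
        df <- data.frame(y = factor(y, levels = c(0L, 1L)), X)
        rpart::rpart(y ~ ., df, method = "class")
      },
      predict = function(m, X)
        as.integer(as.character(predict(m, data.frame(X), type = "class"))),
      score = function(m, X) predict(m, data.frame(X), type = "prob")[, "1"]),
    MLP = list(
      name = "MLP", available = function() requireNamespace("nnet", quietly = TRUE),
      fit = function(X, y, seed) with_seed(seed,
        nnet::nnet(X, y, size = 8L, decay = 1e-3, maxit = 300L,
                   entropy = TRUE, trace = FALSE)),
      predict = function(m, X) as.integer(predict(m, X) > 0.5),
      score = function(m, X) as.numeric(predict(m, X))),
    RF = list(
      name = "RF", available = function() requireNamespace("randomForest", quietly = TRUE),
      fit = function(X, y, seed) with_seed(seed,
        randomForest::randomForest(X, factor(y, levels = c(0L, 1L)), ntree = 200L)),
      predict = function(m, X) as.integer(as.character(predict(m, X))),
      score = function(m, X) predict(m, X, type = "prob")[, "1"]),
    XGB = list(
      name = "XGB", available = function() requireNamespace("xgboost", quietly = TRUE),
      fit = function(X, y, seed) with_seed(seed,
        xgboost::xgboost(data = X, label = y, nrounds = 50L, verbose = 0,
                         nthread = 1L, objective = "binary:logistic")),
      predict = function(m, X) as.integer(predict(m, X) > 0.5),
      score = function(m, X) as.numeric(predict(m, X))),
    SVM = list(
      name = "SVM", available = function() TRUE,
      fit = function(X, y, seed) train_svm(X, y, C = 1.0),
      predict = function(m, X) predict(m, X, type = "class"),
      score = function(m, X) predict(m, X, type = "score"))
  )
}

#' Feature-by-classifier comparison grid
#'
#' Cross-validates every (feature set, learner, LDA on/off) combination on
#' identical fold assignments, so the cells are directly comparable. The
#' LDA axis reproduces the dimensionality-reduction ablation: with
#' `use_lda = TRUE` each learner sees the fold-local 1-D Fisher
#' projection; with `FALSE` it sees the (standardized) raw features.
#'
#' @param feature_sets named list of n x d feature matrices over the same
#'   samples in the same row order.
#' @param y binary labels.
#' @param learners named list of learner specs (default
#'   [builtin_learners()]).
#' @param k,seed,stratify cross-validation protocol.
#' @param use_lda logical vector of LDA settings to sweep (default
#'   `c(TRUE, FALSE)`).
#' @param ridge,standardize LDA options.
#' @return data frame: one row per grid cell with mean metrics; skipped
#'   cells (unavailable learner) carry `NA` metrics and `skipped = TRUE`.
#' @export
comparison_grid <- function(feature_sets, y, learners = builtin_learners(),
                            k = 10L, seed = 1L, stratify = TRUE,
                            use_lda = c(TRUE, FALSE), ridge = NULL,
                            standardize = TRUE) {
  stopifnot(is.list(feature_sets), length(names(feature_sets)) == length(feature_sets))
  y <- as.integer(y)
  fold <- stratified_folds(y, k = k, seed = seed, stratify = stratify)
  out <- list()
  for (fname in names(feature_sets)) {
    X <- as.matrix(feature_sets[[fname]])
    stopifnot(nrow(X) == length(y))
    for (lname in names(learners)) {
      lrn <- learners[[lname]]
      for (lda_on in use_lda) {
        cell <- data.frame(feature = fname, learner = lrn$name, lda = lda_on,
                           ACC = NA_real_, Precision = NA_real_, Recall = NA_real_,
                           F_score = NA_real_, AUC = NA_real_, skipped = TRUE)
        if (lrn$available()) {
          mets <- matrix(NA_real_, k, 5L)
          for (f in seq_len(k)) {
            tr <- fold != f
            Xtr <- X[tr, , drop = FALSE]; Xte <- X[!tr, , drop = FALSE]
            if (lda_on) {
              lda <- fit_lda(Xtr, y[tr], ridge = ridge, standardize = standardize)
              Xtr <- matrix(predict(lda, Xtr), ncol = 1L)
              Xte <- matrix(predict(lda, Xte), ncol = 1L)
            } else if (standardize) {
              ctr <- colMeans(Xtr); scl <- apply(Xtr, 2L, sd)
              scl[scl == 0 | !is.finite(scl)] <- 1
              Xtr <- sweep(sweep(Xtr, 2L, ctr), 2L, scl, "/")
              Xte <- sweep(sweep(Xte, 2L, ctr), 2L, scl, "/")
            }
            colnames(Xtr) <- colnames(Xte) <- paste0("f", seq_len(ncol(Xtr)))
            m <- lrn$fit(Xtr, y[tr], seed + f)
            met <- class_metrics(confusion(y[!tr], lrn$predict(m, Xte)))
            auc <- if (length(unique(y[!tr])) == 2L)
              roc_auc(y[!tr], lrn$score(m, Xte)) else NA_real_
            mets[f, ] <- c(met, auc)
          }
          mm <- colMeans(mets, na.rm = TRUE)
          cell[c("ACC", "Precision", "Recall", "F_score", "AUC")] <- as.list(mm)
          cell$skipped <- FALSE
        }
        out[[length(out) + 1L]] <- cell
      }
    }
  }
  res <- do.call(rbind, out)
  attr(res, "fold_assignment") <- fold
  res
}
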