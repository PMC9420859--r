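#' Train a linear soft-margin SVM base learner
#'
#' Thin wrapper around the `e1071` SVC solver with a linear kernel and
#' penalty `C` (default 1.0). The quadratic program is delegated to
#' `e1071::svm`; the fitted separator is reduced to its explicit linear
#' form `f(x) = w'x + b`, oriented so that larger decision scores mean
#' higher class-1 (moonlighting) confidence. Labels are
#' `as.integer(score > 0)`, identical to the solver's own sign rule.
#'
#' @param X n x p numeric matrix.
#' @param y length-n binary labels (0/1), both classes present.
#' @param C penalty parameter, > 0.
#' @return object of class `moon_svm` with `w`, `b`, `flip`, `C`.
#' @export
train_svm <- function(X, y, C = 1.0) {
  X <- as.matrix(X)
  y <- as.integer(y)
  stopifnot(nrow(X) == length(y), all(y %in% c(0L, 1L)), C > 0)
  if (length(unique(y)) < 2L) stop("train_svm needs samples from both classes", call. = FALSE)
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  fit <- e1071::svm(X, factor(y, levels = c(0L, 1L)), kernel = "linear",
                    cost = C, scale = FALSE)
  w <- as.numeric(crossprod(fit$coefs, fit$SV))
  b <- -fit$rho
  # e1071's decision value is positive for the class named first in the
  # "a/b" column label; flip so positive always means class 1
  dv <- attr(predict(fit, X[1, , drop = FALSE], decision.values = TRUE), "decision.values")
  first <- sub("/.*$", "", colnames(dv)[1])
  flip <- if (identical(first, "1")) 1 else -1
  structure(list(w = w, b = b, flip = flip, C = C, p = ncol(X)), class = "moon_svm")
}

svm_score <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != model$p)
    stop(sprintf("dimension mismatch: member expects %d features, got %d",
                 model$p, ncol(X)), call. = FALSE)
  model$flip * (as.numeric(X %*% model$w) + model$b)
}

#' Predict with a single linear SVM
#'
#' @param object a `moon_svm`.
#' @param newdata m x p matrix.
#' @param type `"class"` for 0/1 labels, `"score"` for signed decision
#'   values (monotone in class-1 confidence).
#' @param ... unused.
#' @return integer labels or numeric scores.
#' @export
predict.moon_svm <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  s <- svm_score(object, newdata)
  if (type == "score") s else as.integer(s > 0)
}

#' Train a bagging ensemble of linear SVMs
#'
#' Bootstrap aggregating: each of `n_members` members is trained on a
#' bootstrap sample of size `ceiling(sample_fraction * n)` drawn with
#' replacement from the training set, using an independent seed-derived
#' substream. Draws that miss one of the two classes are rejected and
#' redrawn (at most 100 attempts, then an error — this happens only with
#' a vanishing minority class). Predictions aggregate members by majority
#' vote; even-split ties fall back to the sign of the mean decision score.
#'
#' @param X n x p numeric matrix.
#' @param y length-n binary labels (0/1).
#' @param n_members ensemble size (default 10).
#' @param sample_fraction bootstrap size as a fraction of n (default 1.0).
#' @param C SVM penalty.
#' @param seed integer; the entire ensemble is a deterministic function of
#'   `(seed, data)`.
#' @return object of class `moon_bagging`.
#' @export
train_bagging <- function(X, y, n_members = 10L, sample_fraction = 1.0,
                          C = 1.0, seed = 1L) {
  X <- as.matrix(X)
  y <- as.integer(y)
  stopifnot(n_members >= 1L, sample_fraction > 0, sample_fraction <= 1)
  if (length(unique(y)) < 2L) stop("train_bagging needs samples from both classes", call. = FALSE)
  n <- nrow(X)
  m <- ceiling(sample_fraction * n)
  member_seeds <- with_seed(seed, sample.int(2^31 - 2L, n_members))
  members <- lapply(seq_len(n_members), function(i) {
    idx <- with_seed(member_seeds[i], {
      for (attempt in 1:100) {
        cand <- sample.int(n, m, replace = TRUE)
        if (length(unique(y[cand])) == 2L) break
        cand <- NULL
      }
      cand
    })
    if (is.null(idx))
      stop("bootstrap draws kept missing a class after 100 attempts; ",
           "the minority class is too small for bagging at this sample_fraction",
           call. = FALSE)
    train_svm(X[idx, , drop = FALSE], y[idx], C = C)
  })
  structure(list(members = members,
                 config = list(n_members = as.integer(n_members),
                               sample_fraction = sample_fraction, C = C,
                               seed = as.integer(seed))),
            class = "moon_bagging")
}

#' Predict with a bagging ensemble
#'
#' @param object a `moon_bagging`.
#' @param newdata m x p matrix.
#' @param soft if `TRUE`, labels come from the sign of the mean decision
#'   score (soft voting) instead of the hard majority vote.
#' @param ... unused.
#' @return data frame with columns `label` (0/1 majority vote; ties broken
#'   by the sign of the mean score) and `score` (mean member decision
#'   score, used for AUC).
#' @export
predict.moon_bagging <- function(object, newdata, soft = FALSE, ...) {
  votes <- vapply(object$members, function(mm) predict(mm, newdata, type = "class"),
                  integer(nrow(as.matrix(newdata))))
  scores <- vapply(object$members, function(mm) svm_score(mm, newdata),
                   numeric(nrow(as.matrix(newdata))))
  votes <- matrix(votes, ncol = length(object$members))
  scores <- matrix(scores, ncol = length(object$members))
  mean_score <- rowMeans(scores)
  k <- length(object$members)
  ones <- rowSums(votes)
  label <- if (soft) as.integer(mean_score > 0)
           else ifelse(ones * 2L == k, as.integer(mean_score > 0), as.integer(ones * 2L > k))
  data.frame(label = as.integer(label), score = mean_score)
}

# ---- end-to-end pipeline ----------------------------------------------

#' Fit the full classification pipeline on a feature matrix
#'
#' Chains the supervised steps applied to an encoded feature matrix:
#' optional per-column z-scoring, the Fisher LDA projection to 1-D, and
#' either a bagging-SVM ensemble or a single linear SVM. All statistics
#' (column means/SDs, scatter matrices) are estimated from the training
#' data passed here, so fitting inside each cross-validation fold is
#' leakage-free.
#'
#' @param X n x d feature matrix (rownames optional).
#' @param y length-n binary labels (1 = moonlighting).
#' @param use_lda project to 1-D with [fit_lda()] before the SVM
#'   (default `TRUE`).
#' @param standardize z-score features (inside the LDA when `use_lda`).
#' @param ridge LDA ridge, see [fit_lda()].
#' @param bagging use the bagging ensemble (default `TRUE`); `FALSE` =
#'   single SVM.
#' @param n_members,sample_fraction bagging parameters.
#' @param C SVM penalty.
#' @param seed seed for the bootstrap substreams.
#' @return object of class `moon_pipeline`.
#' @export
fit_pipeline <- function(X, y, use_lda = TRUE, standardize = TRUE, ridge = NULL,
                         bagging = TRUE, n_members = 10L, sample_fraction = 1.0,
                         C = 1.0, seed = 1L) {
  X <- as.matrix(X)
  y <- as.integer(y)
  lda <- NULL
  center <- scl <- NULL
  if (use_lda) {
    lda <- fit_lda(X, y, ridge = ridge, standardize = standardize)
    Z <- matrix(predict(lda, X), ncol = 1L)
  } else {
    Z <- X
    if (standardize) {
      center <- colMeans(Z)
      scl <- apply(Z, 2L, sd)
      scl[scl == 0 | !is.finite(scl)] <- 1
      Z <- sweep(sweep(Z, 2L, center), 2L, scl, "/")
    }
  }
  model <- if (bagging)
    train_bagging(Z, y, n_members = n_members, sample_fraction = sample_fraction,
                  C = C, seed = seed)
  else train_svm(Z, y, C = C)
  structure(list(lda = lda, center = center, scale = scl, model = model,
                 config = list(use_lda = use_lda, standardize = standardize,
                               bagging = bagging, n_members = as.integer(n_members),
                               sample_fraction = sample_fraction, C = C,
                               seed = as.integer(seed), d = ncol(X))),
            class = "moon_pipeline")
}

#' Predict moonlighting labels with a fitted pipeline
#'
#' @param object a `moon_pipeline`.
#' @param newdata m x d feature matrix on the same encoder as training.
#' @param ... passed to the ensemble predictor (e.g. `soft = TRUE`).
#' @return data frame with columns `label` and `score`.
#' @export
predict.moon_pipeline <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != object$config$d)
    stop(sprintf("dimension mismatch: pipeline expects %d features, got %d",
                 object$config$d, ncol(X)), call. = FALSE)
  if (!is.null(object$lda)) {
    Z <- matrix(predict(object$lda, X), ncol = 1L)
  } else {
    Z <- X
    if (!is.null(object$center))
      Z <- sweep(sweep(Z, 2L, object$center), 2L, object$scale, "/")
  }
  if (inherits(object$model, "moon_bagging")) {
    predict(object$model, Z, ...)
  } else {
    s <- svm_score(object$model, Z)
    data.frame(label = as.integer(s > 0), score = s)
  }
}

# ---- serialization -----------------------------------------------------

#' Save / load a pipeline model bundle
#'
#' The whole pipeline (standardization constants, LDA projection, linear
#' SVM members, bagging configuration) reduces to plain numeric vectors
#' and is serialized as a single documented JSON file, so training and
#' prediction can run in separate invocations.
#'
#' @param model a `moon_pipeline`.
#' @param path JSON file path.
#' @return `path` invisibly (save); the restored `moon_pipeline` (load).
#' @export
save_pipeline <- function(model, path) {
  stopifnot(inherits(model, "moon_pipeline"))
  ser_member <- function(mm) list(w = mm$w, b = mm$b, flip = mm$flip, C = mm$C, p = mm$p)
  obj <- list(
    format = "moonsvm-pipeline-1",
    config = model$config,
    center = model$center, scale = model$scale,
    lda = if (!is.null(model$lda)) unclass(model$lda),
    members = if (inherits(model$model, "moon_bagging"))
      lapply(model$model$members, ser_member),
    bagging_config = if (inherits(model$model, "moon_bagging")) model$model$config,
    svm = if (inherits(model$model, "moon_svm")) ser_member(model$model))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_pipeline
#' @export
load_pipeline <- function(path) {
  obj <- jsonlite::read_json(path)
  if (!identical(obj$format, "moonsvm-pipeline-1"))
    stop("not a moonsvm pipeline bundle: ", path, call. = FALSE)
  num <- function(x) if (is.null(x)) NULL else as.numeric(unlist(x))
  de_member <- function(mm)
    structure(list(w = num(mm$w), b = num(mm$b), flip = num(mm$flip), C = num(mm$C),
                   p = as.integer(num(mm$p))), class = "moon_svm")
  lda <- NULL
  if (!is.null(obj$lda)) {
    lda <- structure(list(w = num(obj$lda$w), mu0 = num(obj$lda$mu0),
                          mu1 = num(obj$lda$mu1), ridge = num(obj$lda$ridge),
                          d = as.integer(num(obj$lda$d)),
                          center = num(obj$lda$center), scale = num(obj$lda$scale)),
                     class = "moon_lda")
  }
  model <- if (!is.null(obj$members))
    structure(list(members = lapply(obj$members, de_member),
                   config = lapply(obj$bagging_config, unlist)),
              class = "moon_bagging")
  else de_member(obj$svm)
  config <- lapply(obj$config, unlist)
  config$d <- as.integer(config$d)
  structure(list(lda = lda, center = num(obj$center), scale = num(obj$scale),
                 model = model, config = config),
            class = "moon_pipeline")
}
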