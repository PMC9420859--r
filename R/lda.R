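#' Closed-form two-class Fisher linear discriminant
#'
#' Fits the Fisher discriminant direction for binary labels: class means
#' `mu0`, `mu1`, unnormalized within-class scatter
#' `SW = sum_j sum_{x in class j} (x - mu_j)(x - mu_j)^T`, and the
#' projection `w` solving `(SW + ridge * I) w = mu0 - mu1`. `w` maximizes
#' the ratio of between-class to within-class scatter and is used here
#' purely as a supervised 1-D dimensionality reduction; no Gaussian class
#' model is fitted. The scatter matrices are used unnormalized (no 1/N_j
#' factor) — the closed-form direction is identical either way.
#'
#' The direction is oriented so that the class-1 projected mean exceeds the
#' class-0 projected mean, removing the sign ambiguity of the closed form.
#'
#' A small ridge keeps the solve well-posed when `SW` is singular (e.g.
#' d = 188 with few samples per fold); the default is
#' `1e-6 * trace(SW) / d`. With `ridge = 0` an exactly singular `SW` is an
#' error telling the user to set `ridge > 0`.
#'
#' @param X n x d numeric matrix.
#' @param y length-n binary labels (0/1).
#' @param ridge non-negative ridge added to the diagonal of `SW`;
#'   `NULL` (default) = `1e-6 * trace(SW) / d`.
#' @param standardize z-score each column (center/scale estimated from
#'   this data, stored in the model and re-applied by `predict`).
#'   Default `TRUE`: the 188-D blocks mix frequencies and positional
#'   fractions of heterogeneous spread.
#' @return object of class `moon_lda` with elements `w`, `mu0`, `mu1`,
#'   `ridge`, `d`, `center`, `scale`.
#' @export
#' @examples
#' X <- rbind(c(0, 0), c(1, 0), c(0, 1), c(4, 0), c(5, 0), c(4, 1))
#' y <- c(0, 0, 0, 1, 1, 1)
#' m <- fit_lda(X, y, ridge = 0, standardize = FALSE)
#' m$w / max(abs(m$w))  # parallel to (2, 1)
fit_lda <- function(X, y, ridge = NULL, standardize = TRUE) {
  X <- as.matrix(X)
  y <- as.integer(y)
  stopifnot(nrow(X) == length(y), all(y %in% c(0L, 1L)))
  if (length(unique(y)) < 2L)
    stop("fit_lda needs samples from both classes", call. = FALSE)
  d <- ncol(X)
  if (d < 1L) stop("at least one feature column required", call. = FALSE)

  center <- scl <- NULL
  if (standardize) {
    center <- colMeans(X)
    scl <- apply(X, 2L, sd)
    scl[scl == 0 | !is.finite(scl)] <- 1      # constant columns pass through
    X <- sweep(sweep(X, 2L, center), 2L, scl, "/")
  }

  X0 <- X[y == 0L, , drop = FALSE]
  X1 <- X[y == 1L, , drop = FALSE]
  mu0 <- colMeans(X0)
  mu1 <- colMeans(X1)
  SW <- crossprod(sweep(X0, 2L, mu0)) + crossprod(sweep(X1, 2L, mu1))

  if (is.null(ridge)) ridge <- 1e-6 * sum(diag(SW)) / d
  stopifnot(ridge >= 0)
  A <- SW + diag(ridge, d)
  w <- tryCatch(solve(A, mu0 - mu1), error = function(e)
    stop("within-class scatter matrix is singular; set ridge > 0 ",
         "(e.g. fit_lda(..., ridge = 1e-6 * sum(diag(SW)) / d))", call. = FALSE))
  if (!all(is.finite(w)) || all(w == 0))
    stop("degenerate discriminant direction (identical class means?)", call. = FALSE)
  if (sum(w * mu1) < sum(w * mu0)) w <- -w   # class 1 projects higher

  structure(list(w = as.numeric(w), mu0 = as.numeric(mu0), mu1 = as.numeric(mu1),
                 ridge = ridge, d = d, center = center, scale = scl),
            class = "moon_lda")
}

#' Project samples onto the fitted discriminant line
#'
#' @param object a `moon_lda` model.
#' @param newdata m x d matrix (d must match the model).
#' @param ... unused.
#' @return numeric vector of m 1-D projections `w' x_i`.
#' @export
predict.moon_lda <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != object$d)
    stop(sprintf("dimension mismatch: model expects %d columns, got %d",
                 object$d, ncol(X)), call. = FALSE)
  if (!is.null(object$center))
    X <- sweep(sweep(X, 2L, object$center), 2L, object$scale, "/")
  as.numeric(X %*% object$w)
}

#' @export
print.moon_lda <- function(x, ...) {
  cat(sprintf("Fisher LDA projection: d = %d, ridge = %.3g, standardized = %s\n",
              x$d, x$ridge, !is.null(x$center)))
  invisible(x)
}
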