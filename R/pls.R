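#' Partial least squares regression (NIPALS)
#'
#' Compact multi-response PLS2 used as the core of the wavelength
#' selectors. X and Y are column-centered internally; coefficients map raw
#' X to raw Y. When the requested number of components exceeds the rank of
#' X the extraction stops early with a warning.
#'
#' @param X numeric matrix, samples x bands.
#' @param Y numeric response matrix (or vector), samples x responses.
#'   For grade classification use one-hot coding (see [grade_onehot()]).
#' @param n_components latent components, `<= min(samples - 1, bands)`.
#' @return Object of class `pls_fit`: `coefficients` (bands x responses),
#'   `x_center`, `y_center`, `n_components` (as used), score/loading
#'   matrices `T`, `W`, `P`, `Q`.
#' @export
pls_fit <- function(X, Y, n_components) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X); p <- ncol(X); q <- ncol(Y)
  if (nrow(Y) != n) stop("X and Y row counts differ")
  n_components <- as.integer(n_components)
  if (n_components < 1L || n_components > min(n - 1L, p))
    stop("n_components must be in [1, min(samples - 1, bands)]")
  xc <- colMeans(X); yc <- colMeans(Y)
  E <- sweep(X, 2L, xc); F_ <- sweep(Y, 2L, yc)
  W <- P <- matrix(0, p, n_components)
  Q <- matrix(0, q, n_components)
  Tm <- matrix(0, n, n_components)
  tol <- 1e-10 * max(abs(E), 1)
  a_used <- 0L
  for (a in seq_len(n_components)) {
    u <- F_[, which.max(apply(F_, 2L, var)), drop = TRUE]
    if (sqrt(sum(u^2)) < 1e-12) break
    t_old <- rep(Inf, n)
    for (it in 1:500) {
      w <- crossprod(E, u)
      nw <- sqrt(sum(w^2))
      if (nw < tol) break
      w <- w / nw
      t_ <- drop(E %*% w)
      qv <- drop(crossprod(F_, t_)) / sum(t_^2)
      if (sum(qv^2) < 1e-30) break
      u <- drop(F_ %*% qv) / sum(qv^2)
      if (sqrt(sum((t_ - t_old)^2)) < 1e-12 * sqrt(sum(t_^2))) break
      t_old <- t_
    }
    if (nw < tol || sum(t_^2) < tol^2) {
      warning("rank deficiency: using ", a_used, " components")
      break
    }
    p_ <- drop(crossprod(E, t_)) / sum(t_^2)
    E <- E - tcrossprod(t_, p_)
    F_ <- F_ - tcrossprod(t_, qv)
    W[, a] <- w; P[, a] <- p_; Q[, a] <- qv; Tm[, a] <- t_
    a_used <- a
  }
  if (a_used == 0L) stop("no usable latent component (X is constant?)")
  W <- W[, seq_len(a_used), drop = FALSE]
  P <- P[, seq_len(a_used), drop = FALSE]
  Q <- Q[, seq_len(a_used), drop = FALSE]
  Tm <- Tm[, seq_len(a_used), drop = FALSE]
  R <- W %*% solve(crossprod(P, W))
  B <- R %*% t(Q)
  structure(list(coefficients = B, x_center = xc, y_center = yc,
                 n_components = a_used, T = Tm, W = W, P = P, Q = Q),
            class = "pls_fit")
}

#' @param object a `pls_fit`.
#' @param newdata samples x bands matrix.
#' @param ... unused.
#' @rdname pls_fit
#' @export
predict.pls_fit <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  sweep(newdata, 2L, object$x_center) %*% object$coefficients +
    matrix(object$y_center, nrow(newdata), length(object$y_center),
           byrow = TRUE)
}

#' One-hot coding of grade labels
#'
#' @param labels integer grades.
#' @param classes the label set (default the sorted unique labels).
#' @return Indicator matrix, samples x classes.
#' @export
grade_onehot <- function(labels, classes = sort(unique(labels))) {
  Y <- matrix(0, length(labels), length(classes),
              dimnames = list(NULL, as.character(classes)))
  Y[cbind(seq_along(labels), match(labels, classes))] <- 1
  Y
}

#' Cross-validated root-mean-square error of a PLS model
#'
#' k-fold CV with fold assignment fixed by `seed`; the error is pooled over
#' all held-out samples and all response columns:
#' `sqrt(mean((Y - Yhat)^2))`.
#'
#' @param X samples x bands matrix.
#' @param Y response matrix or vector.
#' @param n_components PLS components (capped per training fold).
#' @param n_folds number of folds (>= 2).
#' @param seed integer fold seed.
#' @return RMSECV, a single number.
#' @export
rmsecv <- function(X, Y, n_components, n_folds = 5L, seed = 1L) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  if (n_folds < 2L) stop("n_folds must be >= 2")
  if (n < 2L * n_folds) stop("folds would contain < 2 samples")
  folds <- with_seed(seed, sample(rep(seq_len(n_folds), length.out = n)))
  pred <- matrix(NA_real_, n, ncol(Y))
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    a <- min(n_components, sum(tr) - 1L, ncol(X))
    fit <- pls_fit(X[tr, , drop = FALSE], Y[tr, , drop = FALSE], a)
    pred[!tr, ] <- predict(fit, X[!tr, , drop = FALSE])
  }
  sqrt(mean((Y - pred)^2))
}
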