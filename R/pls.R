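# Single-response partial least squares (PLS1) by NIPALS deflation.
#
# Written as the shared engine for the preprocessing harness, the CARS/UVE
# selectors and the PLSR regressor. X and y are mean-centered; predictor
# scaling is off by default (reflectance bands share units). The fit is
# nested in the number of components: one call yields coefficient vectors
# for every component count up to `ncomp`, which is what makes the
# cross-validated component selection cheap.

#' Fit a PLS1 regression by NIPALS
#'
#' @param X n x p predictor matrix.
#' @param y Response vector, length n.
#' @param ncomp Maximum number of latent components; clamped to
#'   `min(n - 1, p)` with a warning when necessary.
#' @param scale Logical: autoscale predictor columns to unit variance.
#' @return A `pls_fit`: coefficient matrix `coef` (p x ncomp_eff, one column
#'   per component count), intercepts, centers, and the deflation loadings.
#' @export
pls_fit <- function(X, y, ncomp = 10L, scale = FALSE) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n, n >= 2, p >= 1)
  max_comp <- min(n - 1L, p)
  if (ncomp > max_comp) {
    warnf("PLS component count clamped from %d to %d", ncomp, max_comp)
    ncomp <- max_comp
  }
  x_center <- colMeans(X)
  x_scale <- if (scale) {
    s <- apply(X, 2, stats::sd)
    s[s == 0] <- 1
    s
  } else rep(1, p)
  y_center <- mean(y)
  Xc <- sweep(sweep(X, 2, x_center), 2, x_scale, "/")
  yc <- y - y_center

  W <- matrix(0, p, ncomp)
  P <- matrix(0, p, ncomp)
  q <- numeric(ncomp)
  a_used <- 0L
  for (a in seq_len(ncomp)) {
    w <- crossprod(Xc, yc)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-14) break
    w <- w / nw
    t_sc <- Xc %*% w
    tt <- sum(t_sc^2)
    if (tt < 1e-14) break
    p_load <- crossprod(Xc, t_sc) / tt
    q[a] <- sum(t_sc * yc) / tt
    Xc <- Xc - tcrossprod(t_sc, p_load)
    yc <- yc - q[a] * t_sc
    W[, a] <- w
    P[, a] <- p_load
    a_used <- a
  }
  if (a_used == 0L) stopf("PLS found no usable component (X'y is zero)")
  W <- W[, seq_len(a_used), drop = FALSE]
  P <- P[, seq_len(a_used), drop = FALSE]
  q <- q[seq_len(a_used)]
  coef <- matrix(0, p, a_used)
  for (a in seq_len(a_used)) {
    coef[, a] <- W[, 1:a, drop = FALSE] %*%
      solve(crossprod(P[, 1:a, drop = FALSE], W[, 1:a, drop = FALSE]),
            q[1:a])
  }
  coef <- coef / x_scale
  intercept <- y_center - drop(crossprod(x_center, coef))
  structure(list(coef = coef, intercept = intercept, ncomp = a_used,
                 x_center = x_center, x_scale = x_scale,
                 y_center = y_center, W = W, P = P, q = q),
            class = "pls_fit")
}

#' Predict from a PLS1 fit
#'
#' @param object A `pls_fit`.
#' @param newdata n' x p matrix.
#' @param ncomp Component count; `NULL` returns a matrix with one column per
#'   component count (1..ncomp_eff).
#' @param ... Unused.
#' @return Vector (fixed `ncomp`) or matrix of predictions.
#' @export
predict.pls_fit <- function(object, newdata, ncomp = NULL, ...) {
  newdata <- as.matrix(newdata)
  pred <- sweep(newdata %*% object$coef, 2, object$intercept, "+")
  if (is.null(ncomp)) return(pred)
  ncomp <- min(ncomp, object$ncomp)
  drop(pred[, ncomp])
}

# k-fold RMSECV curve over component counts 1..ncomp for PLS1.
# Returns list(rmsecv = vector over component counts, best_ncomp).
pls_rmsecv <- function(X, y, ncomp = 10L, k = 10L, seed = 1L) {
  n <- nrow(X)
  if (k > n) stopf("k-fold CV needs k <= n (k=%d, n=%d)", k, n)
  folds <- with_seed(seed, sample(rep(seq_len(k), length.out = n)))
  max_comp <- min(ncomp, n - ceiling(n / k) - 1L, ncol(X))
  max_comp <- max(max_comp, 1L)
  sse <- numeric(max_comp)
  for (fold in seq_len(k)) {
    test <- folds == fold
    fit <- pls_fit(X[!test, , drop = FALSE], y[!test], ncomp = max_comp)
    pred <- predict(fit, X[test, , drop = FALSE])
    used <- seq_len(min(max_comp, fit$ncomp))
    for (a in seq_len(max_comp)) {
      col <- min(a, fit$ncomp)
      sse[a] <- sse[a] + sum((y[test] - pred[, col])^2)
    }
  }
  rmsecv <- sqrt(sse / n)
  list(rmsecv = rmsecv, best_ncomp = which.min(rmsecv))
}
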