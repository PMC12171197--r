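# Dataset splitting, the four regression back-ends (PLSR, MLR, RF, ANN),
# k-fold cross-validation and the R^2/RMSE metric suite.

#' Split a sample table into calibration and prediction sets
#'
#' Random (default) or water-content-quantile-stratified partition. The two
#' subsets are disjoint and exhaustive, and membership depends only on
#' (n, test_fraction, method, seed).
#'
#' @param table A `sample_table` with >= 5 samples.
#' @param test_fraction Fraction assigned to the prediction set (0 < f < 1).
#' @param method "random" or "stratified" (by water-content quartile).
#' @param seed RNG seed.
#' @return List with `calibration` and `prediction` sample tables.
#' @export
split_table <- function(table, test_fraction = 0.3,
                        method = c("random", "stratified"), seed = 1L) {
  method <- match.arg(method)
  n <- nrow(table$reflectance)
  if (n < 5) stopf("splitting needs >= 5 samples")
  if (test_fraction <= 0 || test_fraction >= 1) {
    stopf("test_fraction must be in (0, 1)")
  }
  n_test <- round(n * test_fraction)
  test_idx <- with_seed(seed, {
    if (method == "random") {
      sample(n, n_test)
    } else {
      q <- cut(table$water_content,
               stats::quantile(table$water_content, probs = seq(0, 1, 0.25)),
               include.lowest = TRUE, labels = FALSE)
      unlist(lapply(split(seq_len(n), q), function(idx) {
        sample(idx, round(length(idx) * test_fraction))
      }), use.names = FALSE)
    }
  })
  cal <- subset_table(table, setdiff(seq_len(n), test_idx))
  pred <- subset_table(table, sort(test_idx))
  cal$role <- rep("calibration", nrow(cal$reflectance))
  pred$role <- rep("prediction", nrow(pred$reflectance))
  list(calibration = cal, prediction = pred)
}

#' Regressor specification
#'
#' Hyperparameters of the four back-ends. Defaults follow common chemometric
#' practice for this workflow: 7 PLS components, a 100-tree random forest
#' with seed 42, and a 4-hidden-layer ReLU network trained for exactly 1000
#' optimizer steps.
#'
#' @param kind "PLSR", "MLR", "RF" or "ANN".
#' @param n_components PLSR latent components (default 7).
#' @param n_trees Random-forest trees (default 100).
#' @param rf_seed Random-forest seed (default 42).
#' @param ann_hidden_layers Hidden-layer widths (default c(64, 32, 16, 8)).
#' @param ann_iterations Full-batch optimizer steps (default 1000).
#' @param ann_seed Network initialization seed (default 42).
#' @return A `regressor_spec`.
#' @export
regressor_spec <- function(kind = c("PLSR", "MLR", "RF", "ANN"),
                           n_components = 7L, n_trees = 100L, rf_seed = 42L,
                           ann_hidden_layers = c(64L, 32L, 16L, 8L),
                           ann_iterations = 1000L, ann_seed = 42L) {
  kind <- match.arg(kind)
  stopifnot(n_components >= 1, n_trees >= 1, ann_iterations >= 1,
            all(ann_hidden_layers >= 1))
  structure(list(kind = kind, n_components = as.integer(n_components),
                 n_trees = as.integer(n_trees), rf_seed = as.integer(rf_seed),
                 ann_hidden_layers = as.integer(ann_hidden_layers),
                 ann_iterations = as.integer(ann_iterations),
                 ann_seed = as.integer(ann_seed)),
            class = "regressor_spec")
}

#' Fit a regression back-end
#'
#' PLSR uses the package's NIPALS PLS1 engine; MLR is ordinary least squares
#' (rank-checked, with collinear columns named on failure); RF wraps
#' \pkg{randomForest} under its fixed seed; ANN is the package's
#' deterministic ReLU network. All fitted models support
#' `predict(model, X')`.
#'
#' @param spec A `regressor_spec`.
#' @param X n x p calibration predictor matrix.
#' @param y Calibration response vector.
#' @return A fitted model of class `hl_model`.
#' @export
fit_regressor <- function(spec, X, y) {
  stopifnot(inherits(spec, "regressor_spec"))
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n)
  fit <- switch(spec$kind,
    PLSR = {
      ncomp <- min(spec$n_components, n - 1L, p)
      if (ncomp < spec$n_components) {
        warnf("PLSR components clamped from %d to %d", spec$n_components, ncomp)
      }
      list(pls = pls_fit(X, y, ncomp = ncomp), ncomp = ncomp)
    },
    MLR = {
      if (n <= p + 1) stopf("MLR needs n > p + 1 (n=%d, p=%d)", n, p)
      if (is.null(colnames(X))) colnames(X) <- sprintf("V%d", seq_len(p))
      A <- cbind(`(Intercept)` = 1, X)
      qr_a <- qr(A)
      if (qr_a$rank < ncol(A)) {
        bad <- colnames(A)[qr_a$pivot[(qr_a$rank + 1):ncol(A)]]
        if (is.null(bad)) bad <- qr_a$pivot[(qr_a$rank + 1):ncol(A)]
        stopf("singular MLR design; collinear columns: %s",
              paste(bad, collapse = ", "))
      }
      list(coef = qr.coef(qr_a, y))
    },
    RF = {
      with_seed(spec$rf_seed, {
        randomForest::randomForest(x = X, y = y, ntree = spec$n_trees)
      })
    },
    ANN = {
      x_center <- colMeans(X)
      x_scale <- apply(X, 2, stats::sd)
      x_scale[x_scale == 0] <- 1
      y_center <- mean(y)
      y_scale <- stats::sd(y)
      if (y_scale == 0) y_scale <- 1
      Xs <- sweep(sweep(X, 2, x_center), 2, x_scale, "/")
      ys <- matrix((y - y_center) / y_scale, ncol = 1)
      par <- mlp_train(Xs, ys, spec$ann_hidden_layers, spec$ann_iterations,
                       spec$ann_seed)
      list(par = par, x_center = x_center, x_scale = x_scale,
           y_center = y_center, y_scale = y_scale)
    })
  structure(list(kind = spec$kind, spec = spec, fit = fit, p = p),
            class = "hl_model")
}

#' @export
predict.hl_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  stopifnot(ncol(X) == object$p)
  switch(object$kind,
         PLSR = predict(object$fit$pls, X, ncomp = object$fit$ncomp),
         MLR = drop(cbind(1, X) %*% object$fit$coef),
         RF = unname(predict(object$fit, X)),
         ANN = {
           f <- object$fit
           Xs <- sweep(sweep(X, 2, f$x_center), 2, f$x_scale, "/")
           drop(mlp_forward(f$par, Xs)[[length(f$par$W) + 1]]) *
             f$y_scale + f$y_center
         })
}

#' @export
print.hl_model <- function(x, ...) {
  cat(sprintf("<hl_model> %s on %d predictors\n", x$kind, x$p))
  invisible(x)
}

#' k-fold cross-validation of a regressor
#'
#' Folds of size differing by at most one; out-of-fold predictions are
#' pooled, RMSECV is the root mean squared out-of-fold error, and R_cv^2 is
#' computed on the pooled predictions.
#'
#' @param spec A `regressor_spec`.
#' @param X,y Data.
#' @param k Folds (2 <= k <= n, default 10).
#' @param seed Fold-assignment seed.
#' @return List with `r2_cv`, `rmsecv`, and the pooled `predictions`.
#' @export
kfold_cv <- function(spec, X, y, k = 10L, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (k < 2) stopf("k must be >= 2")
  if (k > n) stopf("k (%d) exceeds n (%d)", k, n)
  folds <- with_seed(seed, sample(rep(seq_len(k), length.out = n)))
  pred <- numeric(n)
  for (fold in seq_len(k)) {
    test <- folds == fold
    model <- fit_regressor(spec, X[!test, , drop = FALSE], y[!test])
    pred[test] <- predict(model, X[test, , drop = FALSE])
  }
  list(r2_cv = r_squared(y, pred), rmsecv = rmse(y, pred), predictions = pred)
}

#' Evaluate a fitted model on a data set
#'
#' @param model A fitted `hl_model` (or any object with a `predict` method
#'   taking a matrix).
#' @param X,y Evaluation set (non-empty; y must have positive variance).
#' @return List with `r2` and `rmse`.
#' @export
evaluate <- function(model, X, y) {
  if (length(y) == 0) stopf("empty evaluation set")
  pred <- predict(model, as.matrix(X))
  list(r2 = r_squared(y, pred), rmse = rmse(y, pred))
}
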