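# Spectral preprocessing: SNV, MSC, Savitzky-Golay, min-max normalization,
# first derivative, the SG+X combinations, and the PLSR harness that ranks
# them by 10-fold cross-validation.

#' Standard normal variate
#'
#' Centers each spectrum (row) to mean zero and scales it to unit sample
#' standard deviation (n-1 denominator), removing per-spectrum offset and
#' gain before modeling.
#'
#' @param X samples x bands matrix.
#' @return Matrix of the same shape.
#' @export
snv <- function(X) {
  X <- as.matrix(X)
  s <- apply(X, 1, stats::sd)
  if (any(s == 0)) {
    stopf("SNV undefined for constant spectra (rows: %s)",
          paste(utils::head(which(s == 0), 5), collapse = ", "))
  }
  (X - rowMeans(X)) / s
}

#' Multiplicative scatter correction
#'
#' Regresses each spectrum on a reference spectrum, `x ~ a + b * reference`,
#' and returns `(x - a) / b`, undoing per-spectrum additive and
#' multiplicative scatter. The reference defaults to the column-mean
#' spectrum of `X`; pass the frozen calibration-set mean when correcting
#' validation or external spectra to avoid information leakage.
#'
#' @param X samples x bands matrix (>= 2 bands).
#' @param reference Optional reference spectrum (length = bands).
#' @return Corrected matrix with the reference stored in
#'   `attr(, "reference")` and slopes in `attr(, "b")`.
#' @export
msc <- function(X, reference = NULL) {
  X <- as.matrix(X)
  if (ncol(X) < 2) stopf("MSC needs >= 2 bands")
  if (is.null(reference)) reference <- colMeans(X)
  stopifnot(length(reference) == ncol(X))
  ref_c <- reference - mean(reference)
  denom <- sum(ref_c^2)
  if (denom == 0) stopf("MSC reference spectrum is constant")
  b <- drop((X - rowMeans(X)) %*% ref_c) / denom
  bad <- which(abs(b) < 1e-12)
  if (length(bad) > 0) {
    stopf("MSC slope ~ 0 for rows: %s", paste(utils::head(bad, 5), collapse = ", "))
  }
  a <- rowMeans(X) - b * mean(reference)
  out <- (X - a) / b
  attr(out, "reference") <- reference
  attr(out, "b") <- b
  out
}

# Savitzky-Golay coefficient solve for one window of wavelengths.
sg_window_fit <- function(lambda_win, center_nm, polyorder, deriv_order) {
  A <- outer(lambda_win - center_nm, 0:polyorder, "^")
  # row of the pseudo-inverse giving the deriv_order-th polynomial coefficient
  coefs <- solve(crossprod(A), t(A))[deriv_order + 1, ]
  coefs * factorial(deriv_order)
}

#' Savitzky-Golay filtering on a wavelength grid
#'
#' Local least-squares polynomial filtering of each spectrum. The polynomial
#' is fitted in wavelength units, so derivative outputs are per nm (and per
#' nm^2 for order 2), valid on non-uniform grids. Edges are handled by
#' refitting on the truncated window rather than padding, so the output is
#' defined at every band.
#'
#' @param X samples x bands matrix.
#' @param window Odd window length (bands), <= band count.
#' @param polyorder Polynomial degree, < window.
#' @param deriv_order Derivative order (0 = smoothing), <= polyorder.
#' @param grid `wavelength_grid` for the columns.
#' @return Filtered matrix.
#' @export
savitzky_golay <- function(X, window = 11L, polyorder = 2L, deriv_order = 0L,
                           grid) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (window %% 2 == 0) stopf("SG window must be odd, got %d", window)
  if (window > p) stopf("SG window (%d) exceeds band count (%d)", window, p)
  if (polyorder >= window) stopf("SG polyorder must be < window")
  if (deriv_order > polyorder) stopf("deriv_order must be <= polyorder")
  lambda <- grid$centers_nm
  stopifnot(length(lambda) == p)
  half <- (window - 1L) %/% 2L
  out <- matrix(0, nrow(X), p)
  for (k in seq_len(p)) {
    lo <- max(1L, k - half)
    hi <- min(p, k + half)
    # truncated-window refit keeps the polynomial order if enough points
    ord <- min(polyorder, hi - lo)
    if (ord < deriv_order) stopf("window too short for derivative at band %d", k)
    w <- sg_window_fit(lambda[lo:hi], lambda[k], ord, deriv_order)
    out[, k] <- X[, lo:hi, drop = FALSE] %*% w
  }
  out
}

#' Per-spectrum min-max normalization
#'
#' Maps each row affinely onto [0, 1].
#'
#' @param X samples x bands matrix with non-constant rows.
#' @return Normalized matrix.
#' @export
normalize_minmax <- function(X) {
  X <- as.matrix(X)
  lo <- apply(X, 1, min)
  hi <- apply(X, 1, max)
  if (any(hi == lo)) {
    stopf("min-max normalization undefined for constant rows: %s",
          paste(utils::head(which(hi == lo), 5), collapse = ", "))
  }
  (X - lo) / (hi - lo)
}

#' First derivative of spectra with respect to wavelength
#'
#' Finite differences divided by the wavelength spacing: central differences
#' on interior bands, one-sided at the two ends. Units nm^-1.
#'
#' @param X samples x bands matrix (>= 2 bands).
#' @param grid `wavelength_grid` for the columns.
#' @return Derivative matrix of the same shape.
#' @export
first_derivative <- function(X, grid) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (p < 2) stopf("first derivative needs >= 2 bands")
  lambda <- grid$centers_nm
  stopifnot(length(lambda) == p)
  out <- matrix(0, nrow(X), p)
  out[, 1] <- (X[, 2] - X[, 1]) / (lambda[2] - lambda[1])
  out[, p] <- (X[, p] - X[, p - 1]) / (lambda[p] - lambda[p - 1])
  if (p > 2) {
    k <- 2:(p - 1)
    out[, k] <- (X[, k + 1, drop = FALSE] - X[, k - 1, drop = FALSE]) /
      rep(lambda[k + 1] - lambda[k - 1], each = nrow(X))
  }
  out
}

PREP_NAMES <- c("none", "SG", "Nor", "SNV", "MSC", "FD",
                "SG+Nor", "SG+SNV", "SG+MSC", "SG+FD")

#' Preprocessing method descriptor
#'
#' @param name One of "none", "SG", "Nor", "SNV", "MSC", "FD", "SG+Nor",
#'   "SG+SNV", "SG+MSC", "SG+FD".
#' @param sg_window,sg_polyorder Savitzky-Golay settings used wherever SG is
#'   part of the method (defaults 11 / 2).
#' @return A `prep_method`.
#' @export
prep_method <- function(name, sg_window = 11L, sg_polyorder = 2L) {
  name <- match.arg(name, PREP_NAMES)
  if (sg_window %% 2 == 0 || sg_window <= sg_polyorder) {
    stopf("sg_window must be odd and > sg_polyorder")
  }
  structure(list(name = name, sg_window = as.integer(sg_window),
                 sg_polyorder = as.integer(sg_polyorder)),
            class = "prep_method")
}

#' Apply a preprocessing method
#'
#' Applies the method to a spectra matrix. For MSC the reference spectrum is
#' taken from `state` when given (the frozen calibration-set mean); the
#' returned attribute `state` carries whatever must be reused on validation
#' or external data.
#'
#' @param method A `prep_method`.
#' @param X samples x bands matrix.
#' @param grid `wavelength_grid`.
#' @param state Optional state from a previous (calibration) application.
#' @return List with `X` (processed matrix) and `state`.
#' @export
apply_prep <- function(method, X, grid, state = NULL) {
  stopifnot(inherits(method, "prep_method"))
  sg <- function(M) savitzky_golay(M, method$sg_window, method$sg_polyorder,
                                   0L, grid)
  base <- switch(method$name,
                 "none" = , "Nor" = , "SNV" = , "MSC" = , "FD" = X,
                 sg(X))
  tail_op <- sub("^SG\\+?", "", method$name)
  if (tail_op %in% c("", "none")) tail_op <- "pass"
  out <- switch(tail_op,
                "pass" = base,
                "Nor" = normalize_minmax(base),
                "SNV" = snv(base),
                "FD" = first_derivative(base, grid),
                "MSC" = {
                  ref <- if (!is.null(state)) state$msc_reference else NULL
                  m <- msc(base, ref)
                  state <- list(msc_reference = attr(m, "reference"))
                  m
                })
  if (tail_op != "MSC") state <- list()
  list(X = out, state = state)
}

#' Rank preprocessing methods with a PLSR harness
#'
#' For each method, preprocesses the table's spectra, fits PLS1 with the
#' component count (1..`max_components`) chosen at the minimum 10-fold
#' RMSECV, and reports calibration R^2/RMSE together with the pooled
#' cross-validation R_cv^2/RMSECV. Fold assignment depends only on
#' (n, k, seed), so two identical methods yield identical rows.
#'
#' @param table A `sample_table` with at least `k` samples.
#' @param methods List of `prep_method` objects (default: the nine standard
#'   methods plus "none").
#' @param max_components Largest PLS component count tried (default 10).
#' @param k CV folds (default 10).
#' @param seed Seed for fold assignment.
#' @return data.frame ranked by RMSECV: method, n_components, r2_cal,
#'   rmse_cal, r2_cv, rmsecv.
#' @export
compare_preprocessing <- function(table, methods = NULL, max_components = 10L,
                                  k = 10L, seed = 1L) {
  if (is.null(methods)) methods <- lapply(PREP_NAMES, prep_method)
  n <- nrow(table$reflectance)
  if (k > n) stopf("k (%d) exceeds sample count (%d)", k, n)
  y <- table$water_content
  folds <- with_seed(seed, sample(rep(seq_len(k), length.out = n)))
  rows <- lapply(methods, function(m) {
    Xp <- apply_prep(m, table$reflectance, table$grid)$X
    max_comp <- min(max_components, n - ceiling(n / k) - 1L, ncol(Xp))
    # out-of-fold predictions for every component count, nested PLS fits
    pred_cv <- matrix(NA_real_, n, max_comp)
    for (fold in seq_len(k)) {
      test <- folds == fold
      fit <- pls_fit(Xp[!test, , drop = FALSE], y[!test], ncomp = max_comp)
      pr <- predict(fit, Xp[test, , drop = FALSE])
      for (a in seq_len(max_comp)) pred_cv[test, a] <- pr[, min(a, fit$ncomp)]
    }
    rmsecv_curve <- sqrt(colMeans((pred_cv - y)^2))
    a_best <- which.min(rmsecv_curve)
    fit_all <- pls_fit(Xp, y, ncomp = a_best)
    pred_cal <- predict(fit_all, Xp, ncomp = a_best)
    data.frame(method = m$name, n_components = a_best,
               r2_cal = r_squared(y, pred_cal),
               rmse_cal = rmse(y, pred_cal),
               r2_cv = r_squared(y, pred_cv[, a_best]),
               rmsecv = rmsecv_curve[a_best])
  })
  out <- do.call(rbind, rows)
  out[order(out$rmsecv), , drop = FALSE]
}
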