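# Vegetation indices for leaf water: the Near-Infrared Slope Difference
# Index (NISDI), the empirical two-band families DVI/RVI/NDVI, exhaustive
# ordered band-pair correlation searches, Pearson screening with a
# two-tailed t test, and univariate linear index -> water-content models.

#' Slope spectrum
#'
#' Rate of change of reflectance with wavelength at each band, in nm^-1:
#' central differences on interior bands, one-sided at the ends.
#'
#' @param spectrum Reflectance vector (>= 3 bands).
#' @param grid `wavelength_grid` matching the spectrum.
#' @return Numeric slope vector (same length).
#' @export
slope <- function(spectrum, grid) {
  p <- length(spectrum)
  if (p < 3) stopf("slope needs >= 3 bands")
  stopifnot(length(grid) == p)
  drop(first_derivative(matrix(spectrum, 1), grid))
}

#' Near-Infrared Slope Difference Index
#'
#' NISDI = 1.3e3 * D(1559 nm) - 1.9 * R(1439 nm), where D is the reflectance
#' slope in nm^-1 on the shoulder of the 1440 nm water absorption band and R
#' the reflectance inside it. The anchors snap to the nearest grid band; the
#' snapped wavelengths are attached as an attribute. Accepts a single
#' spectrum or a samples x bands matrix.
#'
#' @param spectrum Reflectance vector or matrix.
#' @param grid `wavelength_grid` spanning 1439 and 1559 nm.
#' @return Scalar (or vector for a matrix input) with attribute
#'   `anchors_nm` naming the snapped wavelengths.
#' @export
nisdi <- function(spectrum, grid) {
  b_slope <- nearest_band(grid, 1559)
  b_refl <- nearest_band(grid, 1439)
  X <- if (is.matrix(spectrum)) spectrum else matrix(spectrum, 1)
  stopifnot(ncol(X) == length(grid))
  D <- first_derivative(X, grid)
  out <- 1.3e3 * D[, b_slope] - 1.9 * X[, b_refl]
  if (!is.matrix(spectrum)) out <- out[1]
  attr(out, "anchors_nm") <- c(slope_nm = grid$centers_nm[b_slope],
                               refl_nm = grid$centers_nm[b_refl])
  out
}

#' Two-band empirical vegetation index
#'
#' DVI = r_i - r_j; RVI = r_i / r_j; NDVI = (r_i - r_j) / (r_i + r_j),
#' where r_i plays the near-infrared role and r_j the red role. Undefined
#' values (zero denominators) come back as NaN and are excluded pairwise
#' from correlations downstream.
#'
#' @param family "DVI", "RVI" or "NDVI".
#' @param r_i,r_j Reflectance values (vectorized).
#' @return Index values.
#' @export
pair_index <- function(family, r_i, r_j) {
  family <- match.arg(family, c("DVI", "RVI", "NDVI"))
  out <- switch(family,
                DVI = r_i - r_j,
                RVI = r_i / r_j,
                NDVI = (r_i - r_j) / (r_i + r_j))
  out[!is.finite(out)] <- NaN
  out
}

#' Pearson correlation with a two-tailed significance test
#'
#' Sample correlation r with the p-value of t = r * sqrt((n-2) / (1-r^2))
#' against Student's t with n-2 degrees of freedom, two-tailed.
#'
#' @param x,y Numeric vectors of equal length >= 3, both non-constant.
#' @return List with `r`, `p`, `n`.
#' @export
pearson <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stopf("Pearson test needs >= 3 complete observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stopf("constant input to pearson()")
  r <- stats::cor(x, y)
  p <- if (abs(r) >= 1) 0 else {
    t_stat <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(t_stat), df = n - 2)
  }
  list(r = r, p = p, n = n)
}

# correlation of each column of M (may contain NaN) with y, pairwise-complete
col_cor <- function(M, y) {
  ok_all <- colSums(!is.finite(M)) == 0
  r <- rep(NA_real_, ncol(M))
  if (any(ok_all)) {
    Mc <- M[, ok_all, drop = FALSE]
    Mc <- sweep(Mc, 2, colMeans(Mc))
    yc <- y - mean(y)
    denom <- sqrt(colSums(Mc^2) * sum(yc^2))
    r[ok_all] <- ifelse(denom == 0, NA_real_, drop(crossprod(Mc, yc)) / denom)
  }
  for (j in which(!ok_all)) {
    keep <- is.finite(M[, j])
    if (sum(keep) >= 3 && stats::sd(M[keep, j]) > 0 && stats::sd(y[keep]) > 0) {
      r[j] <- stats::cor(M[keep, j], y[keep])
    }
  }
  r
}

#' Exhaustive ordered band-pair index search
#'
#' Computes the chosen two-band index for every ordered band pair (i, j),
#' i != j, correlates it with the table's water content, and returns the
#' full |r| heatmap with the arg-max pair (ties broken by lower i, then
#' lower j). Samples with undefined index values are dropped pairwise; the
#' number of affected pairs is reported.
#'
#' @param table A `sample_table` (>= 3 samples, >= 2 bands).
#' @param family "DVI", "RVI" or "NDVI".
#' @return A `search_result`: `family`, `heatmap` (p x p |r| matrix, NA on
#'   the diagonal), `best_pair` (i, j), `best_abs_r`, `best_p`,
#'   `best_wavelengths_nm`, `n_dropped_pairs`.
#' @export
search_pairs <- function(table, family = c("DVI", "RVI", "NDVI")) {
  family <- match.arg(family)
  X <- table$reflectance
  y <- table$water_content
  if (nrow(X) < 3) stopf("pair search needs >= 3 samples")
  if (stats::sd(y) == 0) stopf("water content is constant; correlations undefined")
  p <- ncol(X)
  heat <- matrix(NA_real_, p, p)
  dropped <- 0L
  for (j in seq_len(p)) {
    M <- pair_index(family, X, X[, j])
    bad <- !is.finite(M)
    if (any(bad)) dropped <- dropped + sum(colSums(bad) > 0)
    r <- col_cor(M, y)
    r[j] <- NA_real_
    heat[, j] <- abs(r)
  }
  best <- which(heat == max(heat, na.rm = TRUE), arr.ind = TRUE)
  best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
  i <- best[1]; j <- best[2]
  idx_vals <- pair_index(family, X[, i], X[, j])
  pr <- pearson(idx_vals, y)
  structure(list(
    family = family,
    heatmap = heat,
    best_pair = c(i = unname(i), j = unname(j)),
    best_abs_r = abs(pr$r),
    best_p = pr$p,
    best_wavelengths_nm = c(table$grid$centers_nm[i], table$grid$centers_nm[j]),
    n_dropped_pairs = dropped
  ), class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  cat(sprintf("<search_result> %s: best pair (%.2f, %.2f) nm, |r| = %.4f, p = %.3g\n",
              x$family, x$best_wavelengths_nm[1], x$best_wavelengths_nm[2],
              x$best_abs_r, x$best_p))
  invisible(x)
}

#' Univariate linear index model for water content
#'
#' Ordinary least squares of water content on an index, `wc ~ a * index + b`
#' (intercept included), with calibration metrics and, when a prediction set
#' is supplied, prediction-set metrics.
#'
#' @param index_values Index values on the calibration set (>= 3).
#' @param wc Calibration water contents.
#' @param pred_index,pred_wc Optional prediction-set index values and water
#'   contents.
#' @return An `index_model`: `coef` (slope a, intercept b), `metrics`
#'   (r2_cal, rmse_cal and, when supplied, r2_pred, rmsep), and a
#'   `predict`-able structure.
#' @export
fit_index_model <- function(index_values, wc, pred_index = NULL, pred_wc = NULL) {
  stopifnot(length(index_values) == length(wc))
  if (length(wc) < 3) stopf("index model needs >= 3 samples")
  if (stats::sd(index_values) == 0) stopf("index has zero variance")
  fit <- stats::lm(wc ~ index_values)
  a <- unname(stats::coef(fit)[2])
  b <- unname(stats::coef(fit)[1])
  pred_cal <- a * index_values + b
  metrics <- list(r2_cal = r_squared(wc, pred_cal), rmse_cal = rmse(wc, pred_cal))
  if (!is.null(pred_index)) {
    stopifnot(length(pred_index) == length(pred_wc))
    pp <- a * pred_index + b
    metrics$r2_pred <- r_squared(pred_wc, pp)
    metrics$rmsep <- rmse(pred_wc, pp)
  }
  structure(list(coef = c(slope = a, intercept = b), metrics = metrics),
            class = "index_model")
}

#' @export
predict.index_model <- function(object, index_values, ...) {
  object$coef[["slope"]] * index_values + object$coef[["intercept"]]
}
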