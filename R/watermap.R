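# Per-pixel water-content mapping: apply a fitted model to every leaf pixel
# of a calibrated cube and render the result as a blue-to-red raster.

#' Feature extractors for per-pixel prediction
#'
#' `nisdi_extractor` turns pixel spectra into a one-column NISDI feature
#' (linear in the spectrum); `band_extractor` selects reflectance at given
#' band indices (also linear). Extractors take `(X, grid)` with X a
#' pixels x bands matrix and return a feature matrix.
#'
#' @param band_indices Integer band indices for `band_extractor`.
#' @return A function of class `feature_extractor`.
#' @export
nisdi_extractor <- function() {
  structure(function(X, grid) {
    v <- nisdi(as.matrix(X), grid)
    matrix(as.numeric(v), ncol = 1)
  }, class = c("feature_extractor", "function"), linear = TRUE)
}

#' @rdname nisdi_extractor
#' @export
band_extractor <- function(band_indices) {
  band_indices <- as.integer(band_indices)
  structure(function(X, grid) {
    if (max(band_indices) > length(grid)) {
      stopf("band index %d outside grid of length %d",
            max(band_indices), length(grid))
    }
    as.matrix(X)[, band_indices, drop = FALSE]
  }, class = c("feature_extractor", "function"), linear = TRUE)
}

#' Predict a per-pixel water-content map
#'
#' Extracts the model's features from every leaf pixel of the cube and
#' predicts water content. Background pixels stay missing. Predictions are
#' stored unclipped; `clip_range` only bounds rendering.
#'
#' @param cube A `hyper_cube` with a leaf mask.
#' @param model A fitted model with a `predict` method over feature matrices
#'   (an `hl_model` or `index_model`).
#' @param feature_extractor A `feature_extractor`; default NISDI.
#' @param model_id Provenance label stored with the map.
#' @param clip_range Display bounds (default c(0, 1)).
#' @return A `water_map`: `values` (rows x cols, NA on background), `mask`,
#'   `model_id`, `clip_range`, `n_out_of_range`.
#' @export
predict_map <- function(cube, model, feature_extractor = nisdi_extractor(),
                        model_id = "model", clip_range = c(0, 1)) {
  if (!any(cube$mask)) stopf("cube mask selects no pixels")
  X <- masked_spectra(cube)
  feats <- feature_extractor(X, cube$grid)
  pred <- if (inherits(model, "index_model")) {
    predict(model, drop(feats[, 1]))
  } else {
    predict(model, feats)
  }
  d <- dim(cube$data)
  values <- matrix(NA_real_, d[1], d[2])
  values[attr(X, "index")] <- pred
  structure(list(values = values, mask = cube$mask, model_id = model_id,
                 clip_range = clip_range,
                 n_out_of_range = sum(pred < clip_range[1] | pred > clip_range[2])),
            class = "water_map")
}

#' @export
print.water_map <- function(x, ...) {
  v <- x$values[x$mask]
  cat(sprintf("<water_map> %d x %d, %d leaf pixels, wc mean %.3f [%.3f, %.3f] (%s)\n",
              nrow(x$values), ncol(x$values), sum(x$mask),
              mean(v), min(v), max(v), x$model_id))
  invisible(x)
}

#' Mean predicted water content over the leaf mask
#'
#' @param map A `water_map`.
#' @return Scalar mean of the masked predictions.
#' @export
map_mean <- function(map) mean(map$values[map$mask])

#' Render a water map to PNG
#'
#' Low water content maps to blue and high to red along a linear ramp over
#' `clip_range`; out-of-range pixels saturate at the end colors; background
#' pixels are neutral gray. A gradient color-scale strip is written next to
#' the image together with a small JSON sidecar holding the numeric bounds.
#' Encoding settings are fixed, so repeated rendering of the same map is
#' byte-identical.
#'
#' @param map A `water_map` with a nonempty mask.
#' @param out_path Output PNG path.
#' @param write_colorbar Write `<out>_colorbar.png` and `<out>_scale.json`.
#' @return Invisibly, `out_path`.
#' @export
render_map <- function(map, out_path, write_colorbar = TRUE) {
  v <- map$values
  if (!any(map$mask) || all(is.na(v))) stopf("water map has no predicted pixels")
  lo <- map$clip_range[1]; hi <- map$clip_range[2]
  t_val <- pmin(pmax((v - lo) / (hi - lo), 0), 1)
  ramp <- grDevices::colorRamp(c("#0000FF", "#FF0000"))
  img <- array(0.5, dim = c(nrow(v), ncol(v), 3))
  idx <- which(!is.na(t_val))
  if (length(idx) > 0) {
    rgb_vals <- ramp(t_val[idx]) / 255
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[idx] <- rgb_vals[, ch]
      img[, , ch] <- plane
    }
  }
  png::writePNG(img, out_path)
  if (write_colorbar) {
    strip <- ramp(seq(1, 0, length.out = 128)) / 255
    bar <- array(0, dim = c(128, 16, 3))
    for (ch in 1:3) bar[, , ch] <- matrix(strip[, ch], 128, 16)
    base <- sub("\\.png$", "", out_path)
    png::writePNG(bar, paste0(base, "_colorbar.png"))
    jsonlite::write_json(list(low = lo, high = hi, low_color = "blue",
                              high_color = "red"),
                         paste0(base, "_scale.json"), auto_unbox = TRUE)
  }
  invisible(out_path)
}
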