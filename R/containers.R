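# Core containers: wavelength grid, calibrated cube, sample table.

#' Wavelength grid
#'
#' Ordered band centers in nm — the coordinate system shared by spectra,
#' cubes and index definitions. Spacing need not be uniform.
#'
#' @param centers_nm Strictly increasing numeric vector, length >= 2.
#' @return A `wavelength_grid`.
#' @export
wavelength_grid <- function(centers_nm) {
  centers_nm <- as.numeric(centers_nm)
  if (length(centers_nm) < 2) stopf("a wavelength grid needs >= 2 bands")
  if (any(diff(centers_nm) <= 0)) stopf("band centers must be strictly increasing")
  structure(list(centers_nm = centers_nm), class = "wavelength_grid")
}

#' @export
length.wavelength_grid <- function(x) length(x$centers_nm)

#' Index of the band nearest a target wavelength
#'
#' @param grid A `wavelength_grid`.
#' @param nm Target wavelength in nm; must lie within the grid's span.
#' @return Integer band index.
#' @export
nearest_band <- function(grid, nm) {
  centers <- grid$centers_nm
  if (nm < min(centers) || nm > max(centers)) {
    stopf("wavelength %g nm outside grid span [%g, %g] nm",
          nm, min(centers), max(centers))
  }
  which.min(abs(centers - nm))
}

#' Hyperspectral reflectance cube
#'
#' @param data rows x cols x bands reflectance array, finite.
#' @param grid `wavelength_grid` matching the band dimension.
#' @param mask Logical leaf mask (TRUE = leaf) with the cube's spatial shape;
#'   defaults to all-TRUE.
#' @return A `hyper_cube`.
#' @export
hyper_cube <- function(data, grid, mask = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (dim(data)[3] != length(grid)) {
    stopf("cube has %d bands but grid has %d", dim(data)[3], length(grid))
  }
  if (!all(is.finite(data))) stopf("cube contains non-finite reflectance")
  if (is.null(mask)) mask <- matrix(TRUE, dim(data)[1], dim(data)[2])
  stopifnot(is.logical(mask))
  if (!all(dim(mask) == dim(data)[1:2])) {
    stopf("mask shape (%d x %d) does not match cube (%d x %d)",
          nrow(mask), ncol(mask), dim(data)[1], dim(data)[2])
  }
  structure(list(data = data, grid = grid, mask = mask), class = "hyper_cube")
}

#' @export
print.hyper_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hyper_cube> %d x %d pixels, %d bands (%.1f-%.1f nm), %d leaf pixels\n",
              d[1], d[2], d[3], min(x$grid$centers_nm), max(x$grid$centers_nm),
              sum(x$mask)))
  invisible(x)
}

#' Sample table of spectra and water contents
#'
#' Pairs a per-sample mean-reflectance matrix with gravimetric water contents
#' and grouping labels.
#'
#' @param sample_ids Character labels, one per row.
#' @param grid `wavelength_grid` matching the reflectance columns.
#' @param reflectance samples x bands numeric matrix.
#' @param water_content Fraction per sample, in [0, 1].
#' @param species Species label per sample (recycled).
#' @param role One of "calibration", "prediction", "external" (recycled).
#' @return A `sample_table`.
#' @export
sample_table <- function(sample_ids, grid, reflectance, water_content,
                         species = "unknown", role = "calibration") {
  reflectance <- as.matrix(reflectance)
  n <- nrow(reflectance)
  if (length(water_content) != n) {
    stopf("reflectance has %d rows but water_content has %d values",
          n, length(water_content))
  }
  if (ncol(reflectance) != length(grid)) {
    stopf("reflectance has %d bands but grid has %d", ncol(reflectance), length(grid))
  }
  if (any(water_content < 0 | water_content > 1)) {
    stopf("water_content values must lie in [0, 1]")
  }
  role <- match.arg(rep(role, length.out = 1),
                    c("calibration", "prediction", "external"))
  structure(list(
    sample_ids = as.character(sample_ids),
    grid = grid,
    reflectance = reflectance,
    water_content = as.numeric(water_content),
    species = rep(as.character(species), length.out = n),
    role = rep(role, length.out = n)
  ), class = "sample_table")
}

#' @export
print.sample_table <- function(x, ...) {
  cat(sprintf("<sample_table> %d samples x %d bands, wc in [%.3f, %.3f], species: %s\n",
              nrow(x$reflectance), ncol(x$reflectance),
              min(x$water_content), max(x$water_content),
              paste(unique(x$species), collapse = ", ")))
  invisible(x)
}

#' Subset a sample table by row
#'
#' @param table A `sample_table`.
#' @param idx Integer or logical row index.
#' @return A `sample_table` with the selected rows.
#' @export
subset_table <- function(table, idx) {
  sample_table(table$sample_ids[idx], table$grid,
               table$reflectance[idx, , drop = FALSE],
               table$water_content[idx],
               table$species[idx], table$role[1])
}

#' Read / write sample tables as CSV
#'
#' Column layout: `sample_id, species, role, wc`, then one reflectance column
#' per band named `wl_<nm>`.
#'
#' @param table A `sample_table`.
#' @param path CSV file path.
#' @return `read_sample_table` returns a `sample_table`;
#'   `write_sample_table` returns `path` invisibly.
#' @export
write_sample_table <- function(table, path) {
  df <- data.frame(sample_id = table$sample_ids, species = table$species,
                   role = table$role, wc = table$water_content,
                   check.names = FALSE)
  refl <- as.data.frame(table$reflectance)
  names(refl) <- sprintf("wl_%.4f", table$grid$centers_nm)
  utils::write.csv(cbind(df, refl), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sample_table
#' @export
read_sample_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  wl_cols <- grep("^wl_", names(df))
  if (length(wl_cols) < 2) stopf("no wl_<nm> reflectance columns found in %s", path)
  grid <- wavelength_grid(as.numeric(sub("^wl_", "", names(df)[wl_cols])))
  sample_table(df$sample_id, grid, as.matrix(df[, wl_cols]), df$wc,
               df$species, df$role[1])
}
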