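# ENVI cube I/O, black/white reflectance calibration, leaf segmentation,
# and mean-spectrum extraction.
#
# ENVI interchange = ASCII header (.hdr) + raw binary cube, interleaved as
# BSQ ([band][line][sample]), BIL ([line][band][sample]) or
# BIP ([line][sample][band]). Pixel coordinates are 0-based externally,
# 1-based inside R; arrays are rows(lines) x cols(samples) x bands.

envi_dtype <- function(code) {
  switch(as.character(code),
         "2" = list(what = "integer", size = 2L, signed = TRUE),
         "3" = list(what = "integer", size = 4L, signed = TRUE),
         "4" = list(what = "double", size = 4L, signed = TRUE),
         "5" = list(what = "double", size = 8L, signed = TRUE),
         "12" = list(what = "integer", size = 2L, signed = FALSE),
         stopf("unsupported ENVI data type %s", code))
}

parse_envi_header <- function(header_path) {
  txt <- readLines(header_path, warn = FALSE)
  if (!grepl("^ENVI", txt[1])) stopf("%s is not an ENVI header", header_path)
  fields <- list()
  key <- NULL
  buf <- character()
  in_brace <- FALSE
  for (line in txt[-1]) {
    if (!in_brace) {
      m <- regmatches(line, regexec("^\\s*([a-zA-Z ][a-zA-Z0-9 ._]*?)\\s*=\\s*(.*)$", line))[[1]]
      if (length(m) == 0) next
      key <- tolower(trimws(m[2]))
      val <- m[3]
      if (startsWith(trimws(val), "{") && !grepl("\\}", val)) {
        in_brace <- TRUE
        buf <- val
      } else {
        fields[[key]] <- trimws(val)
      }
    } else {
      buf <- paste(buf, line)
      if (grepl("\\}", line)) {
        in_brace <- FALSE
        fields[[key]] <- trimws(buf)
      }
    }
  }
  fields
}

header_num_list <- function(fields, key) {
  val <- fields[[key]]
  if (is.null(val)) return(NULL)
  val <- gsub("[{}]", "", val)
  as.numeric(trimws(strsplit(val, ",")[[1]]))
}

#' Read an ENVI hyperspectral cube
#'
#' Supports BSQ/BIL/BIP interleaves and integer/float sample types. The
#' header must declare `samples`, `lines`, `bands`, `interleave`, `data type`
#' and a `wavelength` list whose length matches `bands`.
#'
#' @param header_path Path to the `.hdr` ASCII header.
#' @param data_path Path to the binary cube; defaults to the header path with
#'   its extension dropped, or with `.dat` appended.
#' @return A `hyper_cube` with an all-TRUE mask.
#' @export
read_envi <- function(header_path, data_path = NULL) {
  f <- parse_envi_header(header_path)
  for (key in c("samples", "lines", "bands", "interleave", "data type")) {
    if (is.null(f[[key]])) stopf("ENVI header missing required field '%s'", key)
  }
  wl <- header_num_list(f, "wavelength")
  if (is.null(wl)) stopf("ENVI header missing required field 'wavelength'")
  samples <- as.integer(f[["samples"]])
  lines <- as.integer(f[["lines"]])
  bands <- as.integer(f[["bands"]])
  if (length(wl) != bands) {
    stopf("header declares %d bands but wavelength list has %d entries",
          bands, length(wl))
  }
  interleave <- tolower(f[["interleave"]])
  if (!interleave %in% c("bsq", "bil", "bip")) {
    stopf("unsupported interleave '%s'", interleave)
  }
  dt <- envi_dtype(f[["data type"]])
  endian <- if (!is.null(f[["byte order"]]) && f[["byte order"]] == "1") "big" else "little"
  if (is.null(data_path)) {
    cand <- c(sub("\\.hdr$", "", header_path),
              paste0(sub("\\.hdr$", "", header_path), ".dat"))
    data_path <- cand[file.exists(cand)][1]
    if (is.na(data_path)) stopf("cannot locate binary data for %s", header_path)
  }
  n <- samples * lines * bands
  v <- readBin(data_path, what = dt$what, n = n, size = dt$size,
               signed = dt$signed, endian = endian)
  if (length(v) != n) {
    stopf("binary file %s holds %d values; header implies %d", data_path, length(v), n)
  }
  data <- switch(interleave,
                 bsq = aperm(array(v, c(samples, lines, bands)), c(2, 1, 3)),
                 bil = aperm(array(v, c(samples, bands, lines)), c(3, 1, 2)),
                 bip = aperm(array(v, c(bands, samples, lines)), c(3, 2, 1)))
  hyper_cube(data, wavelength_grid(wl))
}

#' Write an ENVI hyperspectral cube
#'
#' @param cube A `hyper_cube`.
#' @param header_path Output `.hdr` path.
#' @param data_path Output binary path (default: header path minus `.hdr`).
#' @param interleave One of "bsq", "bil", "bip".
#' @param data_type ENVI type code: 4 (float32) or 5 (float64, default,
#'   lossless for R doubles).
#' @return Invisibly, the data path.
#' @export
write_envi <- function(cube, header_path, data_path = NULL,
                       interleave = c("bsq", "bil", "bip"), data_type = 5L) {
  interleave <- match.arg(interleave)
  if (is.null(data_path)) data_path <- sub("\\.hdr$", "", header_path)
  d <- dim(cube$data)
  hdr <- c(
    "ENVI",
    "description = { hyperleaf export }",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    sprintf("data type = %d", data_type),
    sprintf("interleave = %s", interleave),
    "byte order = 0",
    "wavelength units = Nanometers",
    sprintf("wavelength = { %s }",
            paste(sprintf("%.6f", cube$grid$centers_nm), collapse = ", "))
  )
  writeLines(hdr, header_path)
  v <- switch(interleave,
              bsq = as.vector(aperm(cube$data, c(2, 1, 3))),
              bil = as.vector(aperm(cube$data, c(2, 3, 1))),
              bip = as.vector(aperm(cube$data, c(3, 2, 1))))
  size <- if (data_type == 4) 4L else 8L
  writeBin(v, data_path, size = size, endian = "little")
  invisible(data_path)
}

#' Calibration frame set
#'
#' Raw intensity cube plus white-reference and dark-reference frames. The
#' references may be full cubes or single scan lines (samples x bands
#' matrices) that are broadcast along the scan axis, the push-broom
#' convention.
#'
#' @param raw rows x cols x bands raw intensity array.
#' @param white,dark Reference arrays of the same shape, or cols x bands
#'   matrices.
#' @param grid `wavelength_grid` for the band dimension.
#' @return A `calibration_frames` object.
#' @export
calibration_frames <- function(raw, white, dark, grid) {
  stopifnot(is.array(raw), length(dim(raw)) == 3)
  d <- dim(raw)
  if (d[3] != length(grid)) stopf("raw cube bands (%d) != grid length (%d)", d[3], length(grid))
  expand <- function(x, name) {
    if (is.matrix(x)) {
      if (!all(dim(x) == d[2:3])) {
        stopf("%s line frame must be %d x %d (samples x bands)", name, d[2], d[3])
      }
      aperm(array(x, dim = c(d[2], d[3], d[1])), c(3, 1, 2))
    } else {
      stopifnot(all(dim(x) == d))
      x
    }
  }
  structure(list(raw = raw, white = expand(white, "white"),
                 dark = expand(dark, "dark"), grid = grid),
            class = "calibration_frames")
}

#' Black/white reflectance calibration
#'
#' Converts raw intensity to reflectance with the standard two-point
#' calibration \eqn{R = (I - B) / (W - B)}, where W is the white-reference
#' (near-100% reflectance plate) and B the dark-current frame.
#'
#' @param frames A `calibration_frames` object.
#' @return A `hyper_cube` of reflectance (mask all-TRUE).
#' @export
calibrate <- function(frames) {
  stopifnot(inherits(frames, "calibration_frames"))
  denom <- frames$white - frames$dark
  bad <- which(denom <= 0)
  if (length(bad) > 0) {
    idx <- arrayInd(utils::head(bad, 5), dim(denom))
    stopf("white - dark is <= 0 at %d positions, e.g. [row,col,band]: %s",
          length(bad),
          paste(apply(idx, 1, function(r) sprintf("[%d,%d,%d]", r[1], r[2], r[3])),
                collapse = " "))
  }
  hyper_cube((frames$raw - frames$dark) / denom, frames$grid)
}

# Otsu's threshold on a numeric vector (256-bin histogram).
otsu_threshold <- function(x, nbins = 256L) {
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  h <- tabulate(pmin(nbins, 1L + floor((x - rng[1]) / diff(rng) * nbins)), nbins)
  p <- h / sum(h)
  mids <- rng[1] + (seq_len(nbins) - 0.5) / nbins * diff(rng)
  w0 <- cumsum(p)
  mu_t <- sum(p * mids)
  mu0 <- cumsum(p * mids)
  sigma_b <- (mu_t * w0 - mu0)^2 / (w0 * (1 - w0))
  sigma_b[!is.finite(sigma_b)] <- 0
  mids[which.max(sigma_b)]
}

#' Segment leaf pixels from background
#'
#' With labeled training pixels, trains a two-class linear classifier
#' (least-squares discriminant on pixel spectra) and classifies every pixel.
#' Without labels, thresholds a band-ratio contrast image — the ratio of a
#' continuum band (default 1090 nm) to the water absorption band (default
#' 1440 nm), each averaged over `smooth_bands` neighbouring bands — with
#' Otsu's method. Leaves absorb at 1440 nm so their ratio exceeds the
#' background's; the rule is invariant to band-wise rescaling of the cube.
#' If the relative contrast between the two Otsu classes falls below
#' `min_rel_contrast` the scene is declared leaf-free.
#'
#' @param cube A calibrated `hyper_cube`.
#' @param labeled_pixels Optional data.frame with columns `row`, `col`
#'   (1-based) and logical `leaf`.
#' @param ratio_bands_nm Two wavelengths (continuum, absorption) for the
#'   unsupervised ratio rule.
#' @param smooth_bands Half-width in bands of the spectral averaging window.
#' @param min_rel_contrast Minimum relative separation of the Otsu classes
#'   below which an empty mask is returned with a warning.
#' @return Logical mask matrix (TRUE = leaf).
#' @export
segment_leaf <- function(cube, labeled_pixels = NULL,
                         ratio_bands_nm = c(1090, 1440), smooth_bands = 2L,
                         min_rel_contrast = 0.1) {
  d <- dim(cube$data)
  if (!is.null(labeled_pixels)) {
    stopifnot(all(c("row", "col", "leaf") %in% names(labeled_pixels)))
    y <- as.logical(labeled_pixels$leaf)
    if (length(unique(y)) < 2) stopf("training set contains a single class")
    idx <- cbind(labeled_pixels$row, labeled_pixels$col)
    Xtr <- t(vapply(seq_len(nrow(idx)),
                    function(i) cube$data[idx[i, 1], idx[i, 2], ],
                    numeric(d[3])))
    # ridge-regularized two-class linear discriminant: regress +/-1 labels
    # on spectra; the ridge keeps the solve well-posed when the training
    # set is smaller than the band count
    A <- cbind(1, Xtr)
    lambda <- 1e-6 * sum(A^2) / ncol(A)
    beta <- solve(crossprod(A) + diag(lambda, ncol(A)),
                  crossprod(A, ifelse(y, 1, -1)))
    Xall <- matrix(cube$data, d[1] * d[2], d[3])
    score <- drop(cbind(1, Xall) %*% beta)
    return(matrix(score > 0, d[1], d[2]))
  }
  band_a <- nearest_band(cube$grid, ratio_bands_nm[1])
  band_b <- nearest_band(cube$grid, ratio_bands_nm[2])
  win <- function(b) max(1, b - smooth_bands):min(d[3], b + smooth_bands)
  num <- apply(cube$data[, , win(band_a), drop = FALSE], c(1, 2), mean)
  den <- apply(cube$data[, , win(band_b), drop = FALSE], c(1, 2), mean)
  ratio <- num / pmax(den, .Machine$double.eps)
  t0 <- otsu_threshold(as.vector(ratio))
  hi <- ratio > t0
  m_lo <- mean(ratio[!hi])
  m_hi <- mean(ratio[hi])
  if (!any(hi) || !any(!hi) || (m_hi - m_lo) / abs(m_lo) < min_rel_contrast) {
    warnf("no leaf-background contrast found; returning an empty mask")
    return(matrix(FALSE, d[1], d[2]))
  }
  hi
}

#' Mean spectrum over the leaf mask
#'
#' @param cube A `hyper_cube` whose mask has at least one TRUE pixel.
#' @return Per-band arithmetic mean reflectance over masked pixels.
#' @export
mean_spectrum <- function(cube) {
  if (!any(cube$mask)) stopf("mask selects no pixels")
  d <- dim(cube$data)
  X <- matrix(cube$data, d[1] * d[2], d[3])
  colMeans(X[as.vector(cube$mask), , drop = FALSE])
}

#' Extract masked pixel spectra as a matrix
#'
#' @param cube A `hyper_cube`.
#' @return pixels x bands matrix of the masked pixels, with an attribute
#'   `index` giving their positions in the flattened (column-major) image.
#' @export
masked_spectra <- function(cube) {
  d <- dim(cube$data)
  idx <- which(as.vector(cube$mask))
  X <- matrix(cube$data, d[1] * d[2], d[3])[idx, , drop = FALSE]
  attr(X, "index") <- idx
  X
}

#' Write or read a leaf mask as a PNG image
#'
#' @param mask Logical matrix.
#' @param path PNG path.
#' @return `read_mask` returns a logical matrix.
#' @export
write_mask <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img > 0.5
}
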