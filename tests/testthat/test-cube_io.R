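test_that("ENVI cubes round-trip bit-exactly across interleaves", {
  sc <- make_test_cube(2, height = 8, width = 9)
  cube <- hyper_cube(sc$cube$data[, , 1:6], wavelength_grid(sc$cube$grid$centers_nm[1:6]))
  tmp <- withr::local_tempdir()
  reads <- lapply(c("bsq", "bil", "bip"), function(il) {
    hdr <- file.path(tmp, sprintf("c_%s.hdr", il))
    write_envi(cube, hdr, interleave = il)
    read_envi(hdr)
  })
  for (back in reads) {
    expect_identical(back$data, cube$data)
    expect_equal(back$grid$centers_nm, cube$grid$centers_nm, tolerance = 1e-6)
  }
  # float32 path preserves float32-representable data
  cube32 <- hyper_cube(round(cube$data, 3), cube$grid)
  hdr32 <- file.path(tmp, "c32.hdr")
  write_envi(cube32, hdr32, data_type = 4L)
  expect_equal(read_envi(hdr32)$data, cube32$data, tolerance = 1e-6)
})

test_that("ENVI header validation catches malformed files", {
  tmp <- withr::local_tempdir()
  sc <- make_test_cube(3, height = 8, width = 8)
  cube <- hyper_cube(sc$cube$data[, , 1:4], wavelength_grid(sc$cube$grid$centers_nm[1:4]))
  hdr <- file.path(tmp, "c.hdr")
  write_envi(cube, hdr)
  lines <- readLines(hdr)
  # wavelength list shorter than declared bands
  bad1 <- sub("bands = 4", "bands = 5", lines)
  writeLines(bad1, file.path(tmp, "bad1.hdr"))
  file.copy(sub("\\.hdr$", "", hdr), file.path(tmp, "bad1"))
  expect_error(read_envi(file.path(tmp, "bad1.hdr")), "wavelength list has")
  # missing wavelength field is named in the error
  bad2 <- lines[!grepl("^wavelength =", lines)]
  writeLines(bad2, file.path(tmp, "bad2.hdr"))
  file.copy(sub("\\.hdr$", "", hdr), file.path(tmp, "bad2"))
  expect_error(read_envi(file.path(tmp, "bad2.hdr")), "wavelength")
})

test_that("black/white calibration matches its defining identity", {
  g <- wavelength_grid(c(1000, 1100, 1200))
  W <- array(runif(2 * 3 * 3, 5, 9), c(2, 3, 3))
  B <- array(runif(2 * 3 * 3, 0, 1), c(2, 3, 3))
  expect_equal(calibrate(calibration_frames(W, W, B, g))$data,
               array(1, c(2, 3, 3)))
  expect_equal(calibrate(calibration_frames(B, W, B, g))$data,
               array(0, c(2, 3, 3)))
  expect_equal(calibrate(calibration_frames((W + B) / 2, W, B, g))$data,
               array(0.5, c(2, 3, 3)))
  # affine equivariance: I = B + t (W - B)  =>  R == t
  for (t_val in c(-0.5, 0.25, 2)) {
    I <- B + t_val * (W - B)
    expect_equal(calibrate(calibration_frames(I, W, B, g))$data,
                 array(t_val, c(2, 3, 3)), tolerance = 1e-12)
  }
  # single-line reference frames broadcast along the scan axis
  Wl <- matrix(8, 3, 3); Bl <- matrix(2, 3, 3)
  I2 <- array(5, c(4, 3, 3))
  expect_equal(calibrate(calibration_frames(I2, Wl, Bl, g))$data,
               array(0.5, c(4, 3, 3)))
  expect_error(calibrate(calibration_frames(I2, Bl, Wl, g)), "<= 0")
})

test_that("leaf segmentation recovers the true mask", {
  sc <- make_test_cube(7)
  acc_unsup <- mean(segment_leaf(sc$cube) == sc$cube$mask)
  expect_gte(acc_unsup, 0.95)
  # supervised: 20 labeled pixels per class
  leaf_idx <- which(sc$cube$mask, arr.ind = TRUE)
  bg_idx <- which(!sc$cube$mask, arr.ind = TRUE)
  set.seed(1)
  lab <- rbind(
    data.frame(row = leaf_idx[sample(nrow(leaf_idx), 20), 1],
               col = leaf_idx[sample(nrow(leaf_idx), 20), 2], leaf = TRUE),
    data.frame(row = bg_idx[sample(nrow(bg_idx), 20), 1],
               col = bg_idx[sample(nrow(bg_idx), 20), 2], leaf = FALSE))
  acc_sup <- mean(segment_leaf(sc$cube, lab) == sc$cube$mask)
  expect_gte(acc_sup, 0.98)
  expect_error(segment_leaf(sc$cube, lab[lab$leaf, ]), "single class")
})

test_that("ratio-rule segmentation is scale invariant and rejects leaf-free scenes", {
  sc <- make_test_cube(9)
  m1 <- segment_leaf(sc$cube)
  # band-wise constant rescaling of the cube leaves the mask unchanged
  gains <- seq(0.5, 2, length.out = dim(sc$cube$data)[3])
  scaled <- sweep(sc$cube$data, 3, gains, "*")
  m2 <- segment_leaf(hyper_cube(scaled, sc$cube$grid))
  expect_identical(m1, m2)
  bg_only <- hyper_cube(
    array(abs(rnorm(16 * 16 * 224, 0.05, 5e-4)), c(16, 16, 224)),
    sim_grid(sim_config()))
  expect_warning(m3 <- segment_leaf(bg_only), "empty mask")
  expect_equal(sum(m3), 0)
})

test_that("mean spectrum equals the loop mean over masked pixels", {
  sc <- make_test_cube(11, height = 10, width = 12)
  cube <- sc$cube
  ms <- mean_spectrum(cube)
  d <- dim(cube$data)
  loop <- numeric(d[3])
  cnt <- 0
  for (r in seq_len(d[1])) for (c in seq_len(d[2])) {
    if (cube$mask[r, c]) { loop <- loop + cube$data[r, c, ]; cnt <- cnt + 1 }
  }
  expect_equal(ms, loop / cnt, tolerance = 1e-12)
  expect_equal(mean_spectrum(hyper_cube(array(0.4, c(2, 2, 3)),
                                        wavelength_grid(1:3))),
               rep(0.4, 3))
  empty <- hyper_cube(cube$data, cube$grid, matrix(FALSE, d[1], d[2]))
  expect_error(mean_spectrum(empty), "no pixels")
})

test_that("masking commutes with calibration", {
  g <- wavelength_grid(c(1000, 1100, 1200, 1300))
  set.seed(8)
  I <- array(runif(6 * 5 * 4, 2, 6), c(6, 5, 4))
  W <- array(8, c(6, 5, 4)); B <- array(1, c(6, 5, 4))
  mask <- matrix(runif(30) > 0.5, 6, 5)
  R <- calibrate(calibration_frames(I, W, B, g))
  m_after <- mean_spectrum(hyper_cube(R$data, g, mask))
  # mask the raw frames first, then calibrate the masked pixels only
  Xm <- matrix(I, 30, 4)[as.vector(mask), , drop = FALSE]
  m_before <- colMeans((Xm - 1) / (8 - 1))
  expect_equal(m_after, m_before, tolerance = 1e-12)
})

test_that("masks survive the PNG round trip", {
  tmp <- withr::local_tempdir()
  m <- matrix(runif(80) > 0.4, 8, 10)
  p <- file.path(tmp, "mask.png")
  write_mask(m, p)
  expect_identical(read_mask(p), m)
})
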