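grid50 <- wavelength_grid(seq(900, 1700, length.out = 50))

test_that("SNV centers and scales every spectrum with the n-1 convention", {
  expect_equal(snv(matrix(c(1, 2, 3), 1)), matrix(c(-1, 0, 1), 1))
  set.seed(1)
  X <- matrix(runif(8 * 50, 0.2, 0.9), 8, 50)
  S <- snv(X)
  expect_lt(max(abs(rowMeans(S))), 1e-10)
  expect_lt(max(abs(apply(S, 1, sd) - 1)), 1e-10)
  expect_equal(snv(S), S, tolerance = 1e-12)        # idempotence
  # invariance to per-row positive affine transforms
  X2 <- X * 3.2 + 0.7
  expect_equal(snv(X2), S, tolerance = 1e-10)
  expect_error(snv(rbind(X, 0.5)), "constant")
})

test_that("MSC inverts per-spectrum affine scatter against the reference", {
  set.seed(2)
  ref <- colMeans(matrix(runif(6 * 50, 0.2, 0.9), 6, 50))
  X <- rbind(ref, 2 * ref + 0.1, 0.5 * ref - 0.05)
  out <- msc(X, ref)
  for (i in 1:3) expect_equal(unname(out[i, ]), unname(ref), tolerance = 1e-10)
  # random matrix equals the per-row normal-equations oracle
  X <- matrix(runif(10 * 50, 0.1, 1), 10, 50)
  ref <- colMeans(X)
  out <- msc(X, ref)
  for (i in seq_len(nrow(X))) {
    ab <- solve(cbind(1, ref) |> crossprod(), crossprod(cbind(1, ref), X[i, ]))
    expect_equal(out[i, ], (X[i, ] - ab[1]) / ab[2], tolerance = 1e-10)
  }
  # reference = mean spectrum leaves the mean spectrum fixed when rows are
  # affine transforms of a common shape (the pure-scatter family MSC models)
  shape <- colMeans(X)
  Xsc <- t(vapply(1:8, function(i) runif(1, 0.5, 2) * shape + runif(1, -0.1, 0.1),
                  numeric(length(shape))))
  expect_equal(colMeans(msc(Xsc)), colMeans(Xsc), tolerance = 1e-10)
})

test_that("Savitzky-Golay reproduces polynomials and matches the sliding-fit oracle", {
  lam <- grid50$centers_nm
  quad <- 3e-6 * lam^2 - 2e-3 * lam + 1
  expect_equal(savitzky_golay(matrix(quad, 1), 7, 2, 0, grid50),
               matrix(quad, 1), tolerance = 1e-8)
  # first derivative of a linear spectrum is the slope, per nm
  lin <- 0.0015 * lam + 0.2
  d1 <- savitzky_golay(matrix(lin, 1), 7, 2, 1, grid50)
  expect_equal(d1, matrix(0.0015, 1, 50), tolerance = 1e-10)
  # deriv 0 with polyorder = window - 1 is the identity on interior points
  set.seed(3)
  x <- runif(50)
  idt <- savitzky_golay(matrix(x, 1), 5, 4, 0, grid50)
  expect_equal(idt[1, 3:48], x[3:48], tolerance = 1e-8)
  # brute-force local least-squares oracle, including truncated edges
  win <- 9L; ord <- 3L; half <- 4L
  out <- savitzky_golay(matrix(x, 1), win, ord, 0, grid50)
  for (k in seq_len(50)) {
    sel <- max(1, k - half):min(50, k + half)
    fit <- lm(x[sel] ~ poly(lam[sel] - lam[k], degree = min(ord, length(sel) - 1),
                            raw = TRUE))
    expect_equal(out[1, k], unname(coef(fit)[1]), tolerance = 1e-8)
  }
  expect_error(savitzky_golay(matrix(x, 1), 8, 2, 0, grid50), "odd")
})

test_that("min-max normalization and first derivative follow their definitions", {
  expect_equal(normalize_minmax(matrix(c(2, 4, 6), 1)), matrix(c(0, 0.5, 1), 1))
  set.seed(4)
  X <- matrix(runif(5 * 50), 5, 50)
  N <- normalize_minmax(X)
  expect_equal(apply(N, 1, min), rep(0, 5))
  expect_equal(apply(N, 1, max), rep(1, 5))
  expect_equal(normalize_minmax(X * 2 + 3), N, tolerance = 1e-12)
  expect_error(normalize_minmax(matrix(1, 2, 4)), "constant")

  lam <- grid50$centers_nm
  lin <- matrix(0.002 * lam, 2, 50, byrow = TRUE)
  expect_equal(first_derivative(lin, grid50), matrix(0.002, 2, 50),
               tolerance = 1e-12)
  # loop oracle on a random row
  x <- X[1, , drop = FALSE]
  fd <- first_derivative(x, grid50)
  loop <- numeric(50)
  loop[1] <- (x[2] - x[1]) / (lam[2] - lam[1])
  loop[50] <- (x[50] - x[49]) / (lam[50] - lam[49])
  for (k in 2:49) loop[k] <- (x[k + 1] - x[k - 1]) / (lam[k + 1] - lam[k - 1])
  expect_equal(drop(fd), loop, tolerance = 1e-12)
})

test_that("the preprocessing comparison ranks scatter correction above none on scattered data", {
  # with per-spectrum scatter, correction pays off when the component budget
  # is tight: uncorrected models must spend latent components on the scatter
  # subspace instead of the water signal
  cfg <- sim_config(scatter_mult_sd = 0.2, scatter_add_sd = 0.06,
                    noise_sd = 2e-3, n_bands = 60)
  wins <- vapply(1:10, function(s) {
    tab <- simulate_sample_table(80, cfg, seed = 100 + s)
    res <- compare_preprocessing(tab, methods = lapply(c("none", "SNV", "MSC"),
                                                       prep_method),
                                 max_components = 2, seed = s)
    which(res$method == "none") > 1   # some scatter-corrected method ranks above
  }, logical(1))
  expect_gte(sum(wins), 8)
})

test_that("the comparison harness is deterministic and near-exact on noiseless data", {
  cfg <- quiet_config(n_bands = 40)
  tab <- simulate_sample_table(60, cfg, seed = 5)
  # methods that act linearly on spectra recover the noiseless linear
  # relation essentially exactly; amplitude-normalizing methods (SNV, MSC,
  # min-max) necessarily trade some of an amplitude-coded signal away
  res <- compare_preprocessing(tab, methods = lapply(c("none", "SG", "FD"),
                                                     prep_method),
                               max_components = 6, seed = 9)
  expect_true(all(res$r2_cv > 0.999))
  res2 <- compare_preprocessing(tab, methods = list(prep_method("SNV"),
                                                    prep_method("SNV")),
                                max_components = 6, seed = 9)
  expect_equal(res2[1, -1], res2[2, -1], ignore_attr = TRUE)
  expect_error(compare_preprocessing(tab, k = 100), "exceeds sample count")
})

test_that("MSC state freezes the calibration reference for later sets", {
  cfg <- sim_config(n_bands = 30, seed = 6)
  tab <- simulate_sample_table(20, cfg, seed = 6)
  m <- prep_method("MSC")
  cal <- apply_prep(m, tab$reflectance[1:12, ], tab$grid)
  pred <- apply_prep(m, tab$reflectance[13:20, ], tab$grid, cal$state)
  expect_equal(cal$state$msc_reference, colMeans(tab$reflectance[1:12, ]))
  # applying with the frozen reference differs from refitting on the new set
  refit <- apply_prep(m, tab$reflectance[13:20, ], tab$grid)
  expect_false(isTRUE(all.equal(pred$X, refit$X)))
})
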