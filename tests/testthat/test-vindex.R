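test_that("the slope spectrum matches the loop oracle in per-nm units", {
  g <- wavelength_grid(c(1000, 1010, 1025, 1045, 1070))
  lin <- 0.001 * g$centers_nm
  expect_equal(slope(lin, g), rep(0.001, 5), tolerance = 1e-12)
  expect_equal(slope(rep(0.4, 5), g), rep(0, 5))
  set.seed(14)
  x <- runif(5)
  s <- slope(x, g)
  lam <- g$centers_nm
  loop <- c((x[2] - x[1]) / (lam[2] - lam[1]),
            (x[3] - x[1]) / (lam[3] - lam[1]),
            (x[4] - x[2]) / (lam[4] - lam[2]),
            (x[5] - x[3]) / (lam[5] - lam[3]),
            (x[5] - x[4]) / (lam[5] - lam[4]))
  expect_equal(s, loop, tolerance = 1e-12)
  expect_error(slope(c(1, 2), wavelength_grid(c(1, 2))), "3 bands")
})

test_that("NISDI combines the 1559 nm slope and 1439 nm reflectance with its fixed coefficients", {
  # grid aligned so the anchors are exact and the slope at 1559 is controllable
  g <- wavelength_grid(seq(1419, 1579, by = 10))
  spec <- rep(0.5, length(g))
  # flat spectrum: D = 0, R(1439) = 0.5 -> NISDI = -1.9 * 0.5
  expect_equal(as.numeric(nisdi(spec, g)), -0.95, tolerance = 1e-12)
  # pure slope 0.001 per nm with zero reflectance at 1439
  spec2 <- 0.001 * (g$centers_nm - 1439)
  expect_equal(as.numeric(nisdi(spec2, g)), 1.3, tolerance = 1e-12)
  anchors <- attr(nisdi(spec, g), "anchors_nm")
  expect_equal(unname(anchors), c(1559, 1439))
  # grid not covering an anchor names the span
  expect_error(nisdi(rep(1, 4), wavelength_grid(c(1000, 1100, 1200, 1300))),
               "outside grid span")
})

test_that("NISDI is linear in the spectrum and vectorizes over samples", {
  cfg <- sim_config(seed = 15)
  g <- sim_grid(cfg)
  tab <- simulate_sample_table(12, cfg, seed = 15)
  s1 <- tab$reflectance[1, ]; s2 <- tab$reflectance[2, ]
  lhs <- as.numeric(nisdi(0.3 * s1 + 1.7 * s2, g))
  rhs <- 0.3 * as.numeric(nisdi(s1, g)) + 1.7 * as.numeric(nisdi(s2, g))
  expect_equal(lhs, rhs, tolerance = 1e-10)
  vec <- as.numeric(nisdi(tab$reflectance, g))
  per_row <- vapply(seq_len(12), function(i) {
    as.numeric(nisdi(tab$reflectance[i, ], g))
  }, numeric(1))
  expect_equal(vec, per_row, tolerance = 1e-12)
})

test_that("two-band indices follow their definitions and flag undefined values", {
  expect_equal(pair_index("DVI", 0.8, 0.3), 0.5)
  expect_equal(pair_index("RVI", 0.6, 0.2), 3.0)
  expect_equal(pair_index("NDVI", 0.7, 0.7), 0)
  expect_true(is.nan(pair_index("RVI", 0.5, 0)))
  expect_true(is.nan(pair_index("NDVI", 0.5, -0.5)))
})

test_that("Pearson screening matches cor.test", {
  x <- c(1, 2, 3); y <- c(1, 2, 4)
  pr <- pearson(x, y)
  ct <- cor.test(x, y)
  expect_equal(pr$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(pr$p, ct$p.value, tolerance = 1e-12)
  set.seed(16)
  for (i in 1:5) {
    a <- rnorm(20); b <- 0.5 * a + rnorm(20)
    pr <- pearson(a, b); ct <- cor.test(a, b)
    expect_equal(pr$r, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(pr$p, ct$p.value, tolerance = 1e-12)
  }
  expect_equal(pearson(x, x)$r, 1)
  expect_equal(pearson(x, x)$p, 0)
  expect_equal(pearson(x, -x)$r, -1)
  expect_error(pearson(c(1, 1, 1), y), "constant")
})

test_that("pair search heatmaps are symmetric for DVI and NDVI and |r| is wc-scale invariant", {
  cfg <- sim_config(n_bands = 12, seed = 17)
  tab <- simulate_sample_table(30, cfg, seed = 17)
  for (fam in c("DVI", "NDVI")) {
    h <- search_pairs(tab, fam)$heatmap
    expect_equal(h, t(h), tolerance = 1e-12)
  }
  sr1 <- search_pairs(tab, "DVI")
  tab2 <- tab
  tab2$water_content <- 0.9 * tab$water_content + 0.05
  sr2 <- search_pairs(tab2, "DVI")
  expect_equal(sr1$heatmap, sr2$heatmap, tolerance = 1e-10)
  expect_identical(sr1$best_pair, sr2$best_pair)
})

test_that("univariate index models match the closed-form OLS oracle", {
  set.seed(18)
  idx <- rnorm(50)
  wc_frac <- pmin(pmax(0.3 + 0.1 * idx + rnorm(50, 0, 0.02), 0), 1)
  m <- fit_index_model(idx, wc_frac)
  b <- cov(idx, wc_frac) / var(idx)
  a <- mean(wc_frac) - b * mean(idx)
  expect_equal(unname(m$coef["slope"]), b, tolerance = 1e-10)
  expect_equal(unname(m$coef["intercept"]), a, tolerance = 1e-10)
  # exact linear data
  m2 <- fit_index_model(idx, 0.2 * idx + 0.4)
  expect_equal(m2$metrics$r2_cal, 1, tolerance = 1e-12)
  expect_lt(m2$metrics$rmse_cal, 1e-12)
  expect_error(fit_index_model(rep(1, 10), runif(10)), "zero variance")
})

test_that("an index shuffled against water content has no predictive skill", {
  low <- vapply(1:10, function(s) {
    set.seed(400 + s)
    idx <- rnorm(200)
    wc_v <- 0.3 + 0.1 * idx
    shuffled <- sample(idx)
    m <- fit_index_model(shuffled[1:140], wc_v[1:140],
                         shuffled[141:200], wc_v[141:200])
    m$metrics$r2_pred < 0.05
  }, logical(1))
  expect_gte(sum(low), 9)
})
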