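test_that("water content follows the fresh/dry mass relation and round-trips", {
  expect_equal(water_content(2, 1), 0.5)
  expect_equal(water_content(1, 1), 0)
  expect_equal(water_content(4, 1), 0.75)
  expect_error(water_content(1, 0), "dry mass")
  expect_error(water_content(0.5, 1), "mass must be")
  # inversion: mass = G0 / (1 - wc) recovers wc
  for (wc in seq(0, 0.95, by = 0.05)) {
    for (g0 in c(0.3, 1, 7.5)) {
      expect_equal(water_content(g0 / (1 - wc), g0), wc, tolerance = 1e-12)
    }
  }
})

test_that("noiseless spectra decrease with water content in the 1440 nm band", {
  cfg <- quiet_config()
  grid <- sim_grid(cfg)
  b <- nearest_band(grid, 1440)
  wcs <- seq(0.14, 0.77, length.out = 12)
  refl <- vapply(wcs, function(w) simulate_spectrum(w, cfg)[b], numeric(1))
  expect_true(all(diff(refl) < 0))
  # zero water content leaves the bare continuum (absorption depth 0)
  s0 <- simulate_spectrum(0, cfg)
  u <- (grid$centers_nm - cfg$grid_start_nm) / (cfg$grid_end_nm - cfg$grid_start_nm)
  expect_equal(s0, 0.55 + 0.15 * u - 0.10 * u^2, tolerance = 1e-12)
  expect_error(simulate_spectrum(1.2, cfg), "outside")
})

test_that("Monte-Carlo mean spectrum matches the noiseless model", {
  cfg <- sim_config(seed = 10)
  quiet <- quiet_config()
  draws <- with(cfg, t(vapply(seq_len(500), function(i) {
    simulate_spectrum(0.5, cfg, seed = 1000 + i)
  }, numeric(cfg$n_bands))))
  target <- simulate_spectrum(0.5, quiet)
  se <- apply(draws, 2, sd) / sqrt(nrow(draws))
  expect_true(all(abs(colMeans(draws) - target) < 3 * pmax(se, 1e-12) + 1e-8))
})

test_that("sample tables are deterministic and planted modes hold exactly", {
  cfg <- sim_config(seed = 7)
  t1 <- simulate_sample_table(10, cfg, seed = 7)
  t2 <- simulate_sample_table(10, cfg, seed = 7)
  expect_identical(t1$reflectance, t2$reflectance)
  expect_identical(t1$water_content, t2$water_content)
  # planted pair: wc = 2 (R_a - R_b) + 0.1 exactly, |r| = 1
  tp <- simulate_sample_table(40, cfg, planted = planted_pair(30, 90), seed = 3)
  dvi <- tp$reflectance[, 30] - tp$reflectance[, 90]
  expect_equal(tp$water_content, 2 * dvi + 0.1, tolerance = 1e-12)
  expect_equal(abs(cor(tp$water_content, dvi)), 1, tolerance = 1e-12)
})

test_that("sampled water contents match the uniform distribution variance", {
  cfg <- sim_config(seed = 21)
  tab <- simulate_sample_table(600, cfg, seed = 21)
  v_unif <- diff(cfg$wc_range)^2 / 12
  expect_gt(var(tab$water_content), 0.8 * v_unif)
  expect_lt(var(tab$water_content), 1.2 * v_unif)
  expect_true(all(tab$water_content >= cfg$wc_range[1]))
  expect_true(all(tab$water_content <= cfg$wc_range[2]))
})

test_that("drying series decay toward dry mass with consistent water contents", {
  out <- simulate_drying_series("G1", initial_wc = 0.75, dry_mass_g = 1,
                                config = quiet_config(), seed = 5)
  rec <- out$record
  expect_equal(rec$masses_g[1], 4, tolerance = 1e-12)  # 1 / (1 - 0.75)
  expect_true(all(diff(rec$masses_g) < 0))
  expect_true(all(rec$masses_g > rec$dry_mass_g))
  expect_equal(rec$water_contents,
               water_content(rec$masses_g, rec$dry_mass_g))
  expect_true(all(diff(rec$water_contents) <= 0))
  # reflectance in the water band rises step by step as the leaf dries
  b <- nearest_band(out$grid, 1440)
  expect_true(all(diff(out$spectra[, b]) >= 0))
  expect_error(simulate_drying_series("G", 0.5, 1, n_steps = 0), "n_steps")
})

test_that("simulated cubes plant wetter veins and are reproducible", {
  sc1 <- make_test_cube(16, height = 16, width = 16)
  sc2 <- make_test_cube(16, height = 16, width = 16)
  expect_identical(sc1$cube$data, sc2$cube$data)
  expect_identical(sc1$true_wc, sc2$true_wc)
  lam <- sc1$cube$mask & !sc1$veins
  expect_lt(abs(mean(sc1$true_wc[sc1$veins]) - mean(sc1$true_wc[lam]) - 0.1),
            0.02)
  # background spectra come from the distinct low-reflectance model
  bg <- masked_spectra(hyper_cube(sc1$cube$data, sc1$cube$grid, !sc1$cube$mask))
  leaf <- masked_spectra(sc1$cube)
  expect_lt(mean(bg), 0.1)
  expect_gt(mean(leaf), 0.2)
  expect_warning(
    simulate_cube(8, 8, sim_config(seed = 1), lamina_wc = 0.95,
                  vein_offset = 0.2, seed = 1),
    "clipped")
})

test_that("simulation configuration is validated", {
  expect_error(sim_config(n_bands = 3), "n_bands")
  expect_error(sim_config(grid_start_nm = 1700, grid_end_nm = 900), "grid_start")
  expect_error(sim_config(wc_range = c(-0.1, 0.5)), "wc_range")
  expect_error(sim_config(noise_sd = -1), "sd parameters")
  expect_warning(
    simulate_sample_table(5, sim_config(wc_range = c(0.5, 0.5))),
    "degenerate")
})
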