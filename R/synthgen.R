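# Synthetic NIR leaf spectra, drying series, sample tables and image cubes.
#
# The generator emulates the statistical structure of push-broom NIR leaf
# imagery: a smooth continuum whose level rises as leaves dry, Gaussian water
# absorption troughs (the strong first-overtone O-H feature near 1440 nm and
# a weaker one near 1190 nm) whose depth scales with water content,
# per-spectrum multiplicative/additive scatter, and i.i.d. band noise.

#' Simulation configuration
#'
#' Parameters of the synthetic spectrum model. The noiseless model is
#' \deqn{R(\lambda; w) = C(\lambda) - w \sum_k d_k \exp(-(\lambda-\mu_k)^2 / 2\sigma_k^2)}
#' with a quadratic continuum \eqn{C}; a draw then applies
#' \eqn{(1+\epsilon_m) R + \epsilon_a} scatter and additive band noise, and
#' clips at zero. Absorption depth is proportional to water content, so
#' reflectance in the water bands falls as water content rises.
#'
#' @param n_bands Number of spectral bands (default 224).
#' @param grid_start_nm,grid_end_nm Wavelength bounds in nm (default 900-1700).
#' @param wc_range Closed interval of water-content fractions sampled by the
#'   table generator (default c(0.14, 0.77), a typical fresh-to-dry leaf range).
#' @param absorption_centers_nm Water-band centers in nm.
#' @param absorption_widths_nm Gaussian widths (sd, nm) of the bands.
#' @param absorption_depth_per_wc Trough depth per unit water content.
#' @param scatter_mult_sd,scatter_add_sd Multiplicative / additive scatter sd.
#' @param noise_sd Additive i.i.d. band noise sd.
#' @param seed Integer RNG seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_bands = 224L,
                       grid_start_nm = 900,
                       grid_end_nm = 1700,
                       wc_range = c(0.14, 0.77),
                       absorption_centers_nm = c(1440, 1190),
                       absorption_widths_nm = c(65, 40),
                       absorption_depth_per_wc = c(0.55, 0.15),
                       scatter_mult_sd = 0.08,
                       scatter_add_sd = 0.02,
                       noise_sd = 5e-4,
                       seed = 1L) {
  if (n_bands < 4) stopf("n_bands must be >= 4, got %d", n_bands)
  if (!(grid_start_nm < grid_end_nm)) {
    stopf("grid_start_nm (%g) must be < grid_end_nm (%g)", grid_start_nm, grid_end_nm)
  }
  if (length(wc_range) != 2 || wc_range[1] > wc_range[2] ||
      wc_range[1] < 0 || wc_range[2] > 1) {
    stopf("wc_range must be an interval within [0, 1]")
  }
  stopifnot(length(absorption_centers_nm) == length(absorption_widths_nm),
            length(absorption_centers_nm) == length(absorption_depth_per_wc))
  if (any(c(scatter_mult_sd, scatter_add_sd, noise_sd) < 0)) {
    stopf("scatter and noise sd parameters must be >= 0")
  }
  structure(list(
    n_bands = as.integer(n_bands),
    grid_start_nm = grid_start_nm,
    grid_end_nm = grid_end_nm,
    wc_range = wc_range,
    absorption_centers_nm = absorption_centers_nm,
    absorption_widths_nm = absorption_widths_nm,
    absorption_depth_per_wc = absorption_depth_per_wc,
    scatter_mult_sd = scatter_mult_sd,
    scatter_add_sd = scatter_add_sd,
    noise_sd = noise_sd,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Wavelength grid of a simulation configuration
#'
#' Uniform band centers spanning the configured range. All downstream code
#' treats the grid as data and never assumes uniform spacing.
#'
#' @param config A `sim_config`.
#' @return A `wavelength_grid`.
#' @export
sim_grid <- function(config) {
  wavelength_grid(seq(config$grid_start_nm, config$grid_end_nm,
                      length.out = config$n_bands))
}

#' Gravimetric water content from fresh and dry mass
#'
#' Water content is the water fraction of fresh mass,
#' \eqn{M = (G - G_0) / G}, where `mass_g` is the fresh (or partially dried)
#' mass and `dry_mass_g` the constant dry mass.
#'
#' @param mass_g Mass at measurement, grams.
#' @param dry_mass_g Dry mass, grams.
#' @return Water-content fraction in [0, 1). Vectorized.
#' @export
water_content <- function(mass_g, dry_mass_g) {
  if (any(dry_mass_g <= 0)) stopf("dry mass must be positive")
  if (any(mass_g < dry_mass_g)) stopf("mass must be >= dry mass")
  (mass_g - dry_mass_g) / mass_g
}

# Noiseless expected spectrum at a given water content.
noiseless_spectrum <- function(wc, config) {
  lambda <- sim_grid(config)$centers_nm
  u <- (lambda - config$grid_start_nm) / (config$grid_end_nm - config$grid_start_nm)
  continuum <- 0.55 + 0.15 * u - 0.10 * u^2
  absorb <- rep(0, length(lambda))
  for (k in seq_along(config$absorption_centers_nm)) {
    absorb <- absorb + config$absorption_depth_per_wc[k] *
      exp(-(lambda - config$absorption_centers_nm[k])^2 /
            (2 * config$absorption_widths_nm[k]^2))
  }
  pmax(continuum - wc * absorb, 0)
}

#' Simulate a single reflectance spectrum
#'
#' Draws one spectrum at water content `wc`: the noiseless model spectrum,
#' multiplied by `1 + eps_m` and shifted by `eps_a` (per-spectrum scatter),
#' plus i.i.d. band noise, clipped at zero. With all sd parameters zero the
#' draw equals the noiseless model exactly, and reflectance at the band
#' nearest 1440 nm is strictly decreasing in `wc`.
#'
#' @param wc Water-content fraction.
#' @param config A `sim_config`.
#' @param seed Optional seed; `NULL` uses the current RNG stream.
#' @return Numeric reflectance vector of length `config$n_bands`.
#' @export
simulate_spectrum <- function(wc, config, seed = NULL) {
  if (wc < 0 || wc > 1) stopf("water content %g outside [0, 1]", wc)
  with_seed(seed, {
    base <- noiseless_spectrum(wc, config)
    eps_m <- rnorm(1, 0, config$scatter_mult_sd)
    eps_a <- rnorm(1, 0, config$scatter_add_sd)
    noise <- rnorm(length(base), 0, config$noise_sd)
    pmax((1 + eps_m) * base + eps_a + noise, 0)
  })
}

#' Planted-signal specifications for the table generator
#'
#' `planted_pair` makes the table's water content an exact affine function of
#' a two-band reflectance difference, `wc = alpha * (R_a - R_b) + beta`,
#' so exhaustive band-pair searches have a known argmax with |r| = 1 at zero
#' noise. `planted_nisdi` keeps spectra noiseless (so NISDI is an exact affine
#' function of the latent water content) and perturbs the recorded water
#' content so that the fraction of its variance explained by the spectral
#' signal equals `signal_fraction`.
#'
#' @param band_i,band_j Band indices a and b of the planted pair.
#' @param alpha,beta Affine coefficients of the planted relation.
#' @param signal_fraction Target fraction of water-content variance carried
#'   by the spectral signal (default 0.96).
#' @return A planted-signal spec consumed by [simulate_sample_table()].
#' @export
planted_pair <- function(band_i, band_j, alpha = 2, beta = 0.1) {
  structure(list(type = "pair", band_i = as.integer(band_i),
                 band_j = as.integer(band_j), alpha = alpha, beta = beta),
            class = "planted_spec")
}

#' @rdname planted_pair
#' @export
planted_nisdi <- function(signal_fraction = 0.96) {
  stopifnot(signal_fraction > 0, signal_fraction <= 1)
  structure(list(type = "nisdi", signal_fraction = signal_fraction),
            class = "planted_spec")
}

#' Simulate a sample table of spectra with water contents
#'
#' Water contents are drawn uniformly on `config$wc_range`; one spectrum is
#' drawn per sample. A planted-signal spec (see [planted_pair()],
#' [planted_nisdi()]) overrides the water-content column to create an exact
#' or noise-calibrated relation for recovery tests.
#'
#' @param n_samples Number of samples (>= 2).
#' @param config A `sim_config`.
#' @param planted Optional planted-signal spec.
#' @param species Species label stored per sample.
#' @param role One of "calibration", "prediction", "external".
#' @param seed Seed; defaults to `config$seed`.
#' @return A `sample_table`.
#' @export
simulate_sample_table <- function(n_samples, config, planted = NULL,
                                  species = "synthetic", role = "calibration",
                                  seed = config$seed) {
  if (n_samples < 2) stopf("n_samples must be >= 2")
  if (diff(config$wc_range) == 0 && n_samples > 1) {
    warnf("degenerate wc_range of zero width: all samples share one water content")
  }
  grid <- sim_grid(config)
  with_seed(seed, {
    wc <- runif(n_samples, config$wc_range[1], config$wc_range[2])
    cfg <- config
    if (!is.null(planted) && planted$type == "nisdi") {
      # the NISDI-planted mode needs spectra free of scatter/noise so the
      # index is an exact affine function of the latent water content; the
      # pair-planted mode keeps the configured noise (its identity is exact
      # by construction from the realized spectra, and per-sample noise is
      # what makes the planted pair the unique exact one)
      cfg$scatter_mult_sd <- 0
      cfg$scatter_add_sd <- 0
      cfg$noise_sd <- 0
    }
    X <- t(vapply(wc, simulate_spectrum, numeric(config$n_bands), config = cfg))
    if (!is.null(planted)) {
      if (planted$type == "pair") {
        wc <- planted$alpha * (X[, planted$band_i] - X[, planted$band_j]) +
          planted$beta
      } else if (planted$type == "nisdi") {
        f <- planted$signal_fraction
        var_wc <- stats::var(wc)
        noise_sd <- sqrt(var_wc * (1 - f) / f)
        wc <- wc + rnorm(n_samples, 0, noise_sd)
      } else {
        stopf("unknown planted spec type '%s'", planted$type)
      }
    }
    sample_table(
      sample_ids = sprintf("S%04d", seq_len(n_samples)),
      grid = grid,
      reflectance = X,
      water_content = wc,
      species = rep(species, n_samples),
      role = role
    )
  })
}

#' Simulate a stepwise drying series for one leaf group
#'
#' Emulates repeated partial drying and weighing of a leaf group: masses decay
#' geometrically in water mass toward the dry mass over `n_steps` steps, the
#' water content at each step follows from the fresh/dry mass relation, and
#' one spectrum is drawn at each step's water content.
#'
#' @param group_id Label of the leaf group.
#' @param initial_wc Initial water-content fraction, in (0, 1).
#' @param dry_mass_g Dry mass G0 in grams.
#' @param n_steps Number of weighings (default 4).
#' @param config A `sim_config`.
#' @param seed Seed; defaults to `config$seed`.
#' @param retention Per-step water-mass retention factor (default 0.55).
#' @return A list with a `drying_record` and a `spectra` matrix
#'   (`n_steps` x bands).
#' @export
simulate_drying_series <- function(group_id, initial_wc, dry_mass_g,
                                   n_steps = 4L, config = sim_config(),
                                   seed = config$seed, retention = 0.55) {
  if (n_steps < 1) stopf("n_steps must be >= 1")
  if (initial_wc <= 0 || initial_wc >= 1) stopf("initial_wc must be in (0, 1)")
  if (dry_mass_g <= 0) stopf("dry_mass_g must be positive")
  water0 <- dry_mass_g * initial_wc / (1 - initial_wc)
  water <- water0 * retention^(seq_len(n_steps) - 1)
  masses <- dry_mass_g + water
  wc <- water_content(masses, dry_mass_g)
  spectra <- with_seed(seed, {
    t(vapply(wc, simulate_spectrum, numeric(config$n_bands), config = config))
  })
  record <- structure(list(group_id = group_id, masses_g = masses,
                           dry_mass_g = dry_mass_g, water_contents = wc),
                      class = "drying_record")
  list(record = record, spectra = spectra, grid = sim_grid(config))
}

# Procedural vein pattern: a midrib plus symmetric diagonal secondary veins.
vein_pattern <- function(height, width, n_secondary = 4L) {
  veins <- matrix(FALSE, height, width)
  mid <- round(width / 2)
  veins[, pmax(1, pmin(width, c(mid, mid + 1)))] <- TRUE
  anchors <- round(seq(2, height - 1, length.out = n_secondary))
  for (r0 in anchors) {
    for (d in 0:(width - mid)) {
      r <- r0 + round(d * 0.6)
      if (r <= height) {
        veins[r, pmin(width, mid + d)] <- TRUE
        veins[r, pmax(1, mid - d)] <- TRUE
      }
    }
  }
  veins
}

#' Simulate a hyperspectral leaf cube with a ground-truth water map
#'
#' Builds an elliptical leaf on a dark background. Lamina pixels take a base
#' water content plus smooth spatial variation; vein pixels are offset wetter
#' by `vein_offset` (clipped at 1 with a warning). Each pixel's spectrum is
#' drawn from the spectral model at that pixel's true water content;
#' background pixels follow a distinct flat low-reflectance model.
#'
#' @param height,width Spatial dimensions (>= 8).
#' @param config A `sim_config`.
#' @param lamina_wc Base lamina water content (default 0.5).
#' @param vein_offset Water-content excess of veins over lamina (default 0.1).
#' @param spatial_sd Sd of the smooth lamina water-content field (default 0.03).
#' @param seed Seed; defaults to `config$seed`.
#' @return A list: `cube` (a `hyper_cube` with leaf mask), `true_wc`
#'   (height x width matrix, NA on background), `veins` (logical matrix).
#' @export
simulate_cube <- function(height, width, config = sim_config(),
                          lamina_wc = 0.5, vein_offset = 0.1,
                          spatial_sd = 0.03, seed = config$seed) {
  if (height < 8 || width < 8) stopf("height and width must be >= 8")
  grid <- sim_grid(config)
  with_seed(seed, {
    rr <- matrix(seq_len(height), height, width)
    cc <- matrix(seq_len(width), height, width, byrow = TRUE)
    mask <- ((rr - (height + 1) / 2) / (height * 0.42))^2 +
      ((cc - (width + 1) / 2) / (width * 0.42))^2 <= 1
    veins <- vein_pattern(height, width) & mask

    # smooth lamina field: low-frequency sinusoidal mix with random phases
    ph <- runif(4, 0, 2 * pi)
    field <- spatial_sd * (sin(2 * pi * rr / height + ph[1]) *
                             cos(2 * pi * cc / width + ph[2]) +
                             0.5 * sin(4 * pi * cc / width + ph[3] + ph[4]))
    true_wc <- matrix(NA_real_, height, width)
    true_wc[mask] <- lamina_wc + field[mask]
    true_wc[veins] <- true_wc[veins] + vein_offset
    over <- !is.na(true_wc) & true_wc > 1
    if (any(over)) {
      warnf("%d vein pixels clipped to water content 1", sum(over))
      true_wc[over] <- 1
    }
    true_wc[!is.na(true_wc) & true_wc < 0] <- 0

    data <- array(0, dim = c(height, width, config$n_bands))
    idx_leaf <- which(mask)
    for (i in idx_leaf) {
      data[(i - 1) %% height + 1, (i - 1) %/% height + 1, ] <-
        simulate_spectrum(true_wc[i], config)
    }
    idx_bg <- which(!mask)
    for (i in idx_bg) {
      data[(i - 1) %% height + 1, (i - 1) %/% height + 1, ] <-
        pmax(0.05 + rnorm(config$n_bands, 0, config$noise_sd), 0)
    }
    cube <- hyper_cube(data, grid, mask)
    list(cube = cube, true_wc = true_wc, veins = veins)
  })
}
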