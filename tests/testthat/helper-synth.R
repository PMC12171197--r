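# Shared fixture builders. Everything is generated in code at test time.

# noiseless simulation configuration (scatter and band noise off)
quiet_config <- function(...) {
  sim_config(scatter_mult_sd = 0, scatter_add_sd = 0, noise_sd = 0, ...)
}

# planted-signal regression design for selector tests: `n_info` informative
# i.i.d. bands among p, unit effects, small residual noise
make_planted_design <- function(seed, n = 300, p = 100,
                                info = c(10, 30, 50, 70, 90), snr_sd = 0.1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  y <- drop(X[, info] %*% rep(1, length(info))) + rnorm(n, 0, snr_sd)
  list(X = X, y = y, info = info)
}

# constructed design for SPA: four mutually orthogonal large-norm
# informative columns plus twenty smaller-norm nuisance columns lying
# (almost) in their span
make_orthogonal_design <- function(seed, n = 60) {
  set.seed(seed)
  Q <- qr.Q(qr(matrix(rnorm(n * 4), n, 4))) * 10
  C <- matrix(rnorm(4 * 20), 4, 20)
  C <- sweep(C, 2, sqrt(colSums(C^2)), "/") * 0.5
  nuis <- Q %*% C + matrix(rnorm(n * 20, 0, 0.01), n, 20)
  X <- cbind(Q, nuis)
  y <- drop(Q %*% rep(1, 4)) + rnorm(n, 0, 0.01)
  list(X = X, y = y, basis = 1:4)
}

# small random cube with a known elliptical mask and vein structure
make_test_cube <- function(seed = 4, height = 24, width = 24, ...) {
  simulate_cube(height, width, sim_config(seed = seed), seed = seed, ...)
}
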