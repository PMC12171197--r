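# Characteristic-wavelength selection: CARS (competitive adaptive
# reweighted sampling), SPA (successive projections algorithm) and UVE
# (uninformative variable elimination), each returning the selected bands
# with an RMSE/RMSECV diagnostic trace.

new_selection_result <- function(method, selected, grid, trace, settings, seed) {
  selected <- sort(unique(as.integer(selected)))
  stopifnot(length(selected) >= 1)
  structure(list(
    method = method,
    selected_band_indices = selected,
    selected_wavelengths_nm = if (!is.null(grid)) grid$centers_nm[selected] else NULL,
    trace = trace,
    best_trace_value = min(trace, na.rm = TRUE),
    settings = settings,
    seed = seed
  ), class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %s: %d bands, best trace value %.4g\n",
              x$method, length(x$selected_band_indices), x$best_trace_value))
  invisible(x)
}

#' Competitive adaptive reweighted sampling
#'
#' Runs `n_mc` Monte-Carlo iterations. Each iteration fits PLS on a random
#' `sample_fraction` subset of the samples, weights the currently retained
#' variables by their absolute PLS regression coefficients, and reduces the
#' retained count to the exponentially decreasing schedule (all p variables
#' at iteration 1 down to 2 at iteration `n_mc`) by weighted sampling
#' without replacement proportional to |coefficient| — so strong variables
#' compete through to late iterations. The 10-fold RMSECV of each
#' iteration's subset is recorded and the subset at the minimum RMSECV is
#' returned.
#'
#' @param X n x p predictor matrix (p >= 2, n >= k_folds).
#' @param y Response vector.
#' @param grid Optional `wavelength_grid` for reporting wavelengths.
#' @param n_mc Monte-Carlo iterations (default 50).
#' @param k_folds CV folds for the RMSECV trace (default 10).
#' @param sample_fraction Sample fraction per iteration (default 0.8).
#' @param max_pls_components Cap on PLS components; the count is chosen once
#'   by inner 10-fold CV (default cap 10).
#' @param seed RNG seed; the run is a pure function of (X, y, seed).
#' @return A `selection_result` with an RMSECV trace of length `n_mc` and
#'   the per-iteration retained counts in `settings$retained_counts`.
#' @export
cars <- function(X, y, grid = NULL, n_mc = 50L, k_folds = 10L,
                 sample_fraction = 0.8, max_pls_components = 10L, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n < k_folds) stopf("CARS needs n >= k_folds")
  if (p < 2) stopf("CARS needs >= 2 variables")
  ncomp0 <- pls_rmsecv(X, y, ncomp = max_pls_components, k = k_folds,
                       seed = derive_seed(seed, 1))$best_ncomp
  # exponential retention schedule: all p at iteration 1, 2 at iteration n_mc
  k_edf <- log(p / 2) / (n_mc - 1)
  a_edf <- (p / 2)^(1 / (n_mc - 1))
  schedule <- pmax(2L, pmin(p, as.integer(round(p * a_edf * exp(-k_edf * seq_len(n_mc))))))
  n_sub <- max(k_folds, round(sample_fraction * n))

  retained <- seq_len(p)
  rmsecv_trace <- numeric(n_mc)
  retained_counts <- integer(n_mc)
  subsets <- vector("list", n_mc)
  with_seed(derive_seed(seed, 7), {
    for (i in seq_len(n_mc)) {
      idx <- sample(n, n_sub)
      ncomp_i <- min(ncomp0, length(retained), n_sub - 1L)
      fit <- suppressWarnings(
        pls_fit(X[idx, retained, drop = FALSE], y[idx], ncomp = ncomp_i))
      w <- abs(fit$coef[, fit$ncomp])
      n_keep <- min(schedule[i], length(retained))
      if (all(w == 0)) w <- rep(1, length(w))
      keep <- sample(seq_along(retained), n_keep, prob = w / sum(w))
      retained <- sort(retained[keep])
      retained_counts[i] <- length(retained)
      subsets[[i]] <- retained
      # the same fold assignment scores every iteration's subset, so the
      # trace compares subsets rather than fold luck
      cv <- pls_rmsecv(X[, retained, drop = FALSE], y,
                       ncomp = min(ncomp0, length(retained)), k = k_folds,
                       seed = derive_seed(seed, 2))
      rmsecv_trace[i] <- min(cv$rmsecv)
    }
  })
  best_iter <- which.min(rmsecv_trace)
  new_selection_result("CARS", subsets[[best_iter]], grid, rmsecv_trace,
                       list(n_mc = n_mc, k_folds = k_folds,
                            sample_fraction = sample_fraction,
                            n_components = ncomp0, best_iteration = best_iter,
                            edf_schedule = schedule,
                            retained_counts = retained_counts),
                       seed)
}

# Successive-projection chain starting from column `start`.
spa_chain <- function(X, start, chain_len, tol = 1e-10) {
  p <- ncol(X)
  sel <- integer(chain_len)
  sel[1] <- start
  Xp <- X
  for (m in seq_len(chain_len - 1L)) {
    v <- Xp[, sel[m]]
    vv <- sum(v^2)
    if (vv < tol) return(sel[seq_len(m)])
    Xp <- Xp - v %*% (crossprod(v, Xp) / vv)
    norms <- colSums(Xp^2)
    norms[sel[seq_len(m)]] <- -Inf
    if (max(norms) < tol) {
      warnf("SPA chain from band %d truncated at length %d (rank deficiency)",
            start, m)
      return(sel[seq_len(m)])
    }
    sel[m + 1L] <- which.max(norms)
  }
  sel
}

#' Successive projections algorithm
#'
#' For every starting band, grows a chain in which each new variable
#' maximizes the norm of its projection onto the orthogonal complement of
#' the variables already chosen (minimizing collinearity). Every candidate
#' set (start, size) with `min_vars <= size <= max_vars` is scored by the
#' RMSE of a multiple linear regression fitted on a fixed 2/3 calibration
#' split and evaluated on the held-out 1/3; the minimizer is returned.
#'
#' @param X n x p predictor matrix.
#' @param y Response vector.
#' @param grid Optional `wavelength_grid`.
#' @param max_vars Largest candidate set size (default 30; clamped to the
#'   calibration sample count minus 2 and to p).
#' @param min_vars Smallest candidate set size (default 2).
#' @param seed Seed of the calibration/validation split.
#' @return A `selection_result`; `trace` is indexed by variable count (the
#'   best validation RMSE over starts at each size).
#' @export
spa <- function(X, y, grid = NULL, max_vars = 30L, min_vars = 2L, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  n_cal <- round(2 / 3 * n)
  cal_idx <- with_seed(derive_seed(seed, 7), sample(n, n_cal))
  val_idx <- setdiff(seq_len(n), cal_idx)
  max_vars <- min(max_vars, p, n_cal - 2L)
  if (max_vars < min_vars) stopf("max_vars (%d) < min_vars (%d)", max_vars, min_vars)
  Xc <- X[cal_idx, , drop = FALSE]
  yc <- y[cal_idx]
  Xv <- X[val_idx, , drop = FALSE]
  yv <- y[val_idx]

  best <- list(rmse = Inf, sel = NULL)
  trace <- rep(Inf, max_vars)
  for (start in seq_len(p)) {
    chain <- spa_chain(Xc, start, max_vars)
    for (m in seq.int(min_vars, length(chain))) {
      vars <- chain[seq_len(m)]
      A <- cbind(1, Xc[, vars, drop = FALSE])
      coefs <- qr.coef(qr(A), yc)
      coefs[is.na(coefs)] <- 0
      pred <- drop(cbind(1, Xv[, vars, drop = FALSE]) %*% coefs)
      e <- rmse(yv, pred)
      if (e < trace[m]) trace[m] <- e
      if (e < best$rmse) best <- list(rmse = e, sel = vars, start = start)
    }
  }
  trace[!is.finite(trace)] <- NA_real_
  new_selection_result("SPA", best$sel, grid, trace,
                       list(max_vars = max_vars, min_vars = min_vars,
                            start = best$start, split_seed = seed),
                       seed)
}

#' Uninformative variable elimination
#'
#' Appends `n_noise` artificial random-noise variables, fits PLS under
#' resampling (leave-one-out when n <= 200, otherwise 100 Monte-Carlo
#' leave-10%-out rounds) and computes each variable's stability
#' c = mean(b) / sd(b) over the resampled coefficient vectors. Real
#' variables whose |c| does not exceed `cutoff_factor` times the largest
#' noise-variable |c| are eliminated. The survivors are ordered by |c| and
#' the retained count minimizing 10-fold RMSECV is returned.
#'
#' @param X n x p predictor matrix (n >= 10).
#' @param y Response vector.
#' @param grid Optional `wavelength_grid`.
#' @param n_noise Number of appended noise variables (default p).
#' @param noise_scale Scale (sd) of the noise variables (default 1e-10, so
#'   they cannot disturb the model fit; stability is scale-free).
#' @param max_pls_components Cap on PLS components (default 10).
#' @param cutoff_factor Multiplier on the noise stability maximum (default 1).
#' @param k_folds CV folds for the retained-count trace (default 10).
#' @param seed RNG seed.
#' @return A `selection_result`; `trace` is indexed by retained count and
#'   `settings$stability` holds the per-variable stabilities.
#' @export
uve <- function(X, y, grid = NULL, n_noise = ncol(X), noise_scale = 1e-10,
                max_pls_components = 10L, cutoff_factor = 1.0, k_folds = 10L,
                seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n < 10) stopf("UVE needs n >= 10")
  ncomp0 <- pls_rmsecv(X, y, ncomp = max_pls_components, k = k_folds,
                       seed = derive_seed(seed, 1))$best_ncomp
  # internal RNG streams are derived from `seed` so that they cannot
  # collide with a data-generating stream seeded with the same integer
  with_seed(derive_seed(seed, 7), {
    Z <- cbind(X, matrix(stats::rnorm(n * n_noise), n, n_noise) * noise_scale)
    rounds <- if (n <= 200) {
      lapply(seq_len(n), function(i) setdiff(seq_len(n), i))
    } else {
      lapply(seq_len(100L), function(i) sample(n, round(0.9 * n)))
    }
    B <- t(vapply(rounds, function(idx) {
      fit <- pls_fit(Z[idx, , drop = FALSE], y[idx],
                     ncomp = min(ncomp0, length(idx) - 1L))
      fit$coef[, fit$ncomp]
    }, numeric(ncol(Z))))
  })
  b_mean <- colMeans(B)
  b_sd <- apply(B, 2, stats::sd)
  stab <- ifelse(b_sd == 0, ifelse(b_mean == 0, 0, Inf), b_mean / b_sd)
  cutoff <- cutoff_factor * max(abs(stab[(p + 1):(p + n_noise)]))
  real_stab <- abs(stab[seq_len(p)])
  survivors <- which(real_stab > cutoff)
  if (length(survivors) == 0) {
    stopf("no variable exceeds the UVE noise cutoff %.3g; lower cutoff_factor",
          cutoff)
  }
  ord <- survivors[order(real_stab[survivors], decreasing = TRUE)]
  trace <- vapply(seq_along(ord), function(m) {
    vars <- ord[seq_len(m)]
    cv <- pls_rmsecv(X[, vars, drop = FALSE], y,
                     ncomp = min(ncomp0, m), k = k_folds,
                     seed = derive_seed(seed, 200 + m))
    min(cv$rmsecv)
  }, numeric(1))
  m_best <- which.min(trace)
  new_selection_result("UVE", ord[seq_len(m_best)], grid, trace,
                       list(n_noise = n_noise, noise_scale = noise_scale,
                            cutoff_factor = cutoff_factor, cutoff = cutoff,
                            n_components = ncomp0,
                            stability = stab[seq_len(p)],
                            n_survivors = length(survivors)),
                       seed)
}
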