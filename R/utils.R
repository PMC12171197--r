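#' @keywords internal
"_PACKAGE"

# Run `expr` under a local RNG seed, restoring the caller's RNG state.
# All generators route randomness through this so they are pure functions
# of (parameters, seed).
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

# Deterministic fan-out of a parent seed into per-stage child seeds,
# kept below 2^31 so they remain valid R integer seeds.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 10007 + offset) %% .Machine$integer.max)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Root-mean-square error
#'
#' @param observed Numeric vector of reference values.
#' @param predicted Numeric vector of predictions, same length.
#' @return The square root of the mean squared residual.
#' @export
rmse <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted))
  sqrt(mean((observed - predicted)^2))
}

#' Coefficient of determination
#'
#' R^2 = 1 - SS_res / SS_tot with SS_tot taken about the mean of the
#' evaluation set itself (the usual convention for prediction-set R^2).
#'
#' @param observed Numeric vector of reference values.
#' @param predicted Numeric vector of predictions, same length.
#' @return R^2 (at most 1; can be negative for predictions worse than the mean).
#' @export
r_squared <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted))
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot <= 0) stopf("R^2 undefined: reference values have zero variance")
  1 - sum((observed - predicted)^2) / ss_tot
}
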