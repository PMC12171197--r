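# Feed-forward regression network: fully connected, ReLU hidden layers,
# linear output, trained by full-batch Adam for a fixed number of steps.
# Inputs and response are standardized internally; He-uniform initialization
# under a fixed seed makes training fully deterministic.

mlp_init <- function(sizes, seed) {
  with_seed(seed, {
    W <- list(); b <- list()
    for (l in seq_len(length(sizes) - 1)) {
      lim <- sqrt(6 / sizes[l])
      W[[l]] <- matrix(stats::runif(sizes[l] * sizes[l + 1], -lim, lim),
                       sizes[l], sizes[l + 1])
      b[[l]] <- rep(0, sizes[l + 1])
    }
    list(W = W, b = b)
  })
}

mlp_forward <- function(par, X) {
  L <- length(par$W)
  acts <- vector("list", L + 1)
  acts[[1]] <- X
  for (l in seq_len(L)) {
    z <- sweep(acts[[l]] %*% par$W[[l]], 2, par$b[[l]], "+")
    acts[[l + 1]] <- if (l < L) pmax(z, 0) else z
  }
  acts
}

# Full-batch Adam on mean squared error; returns trained parameters.
mlp_train <- function(X, y, hidden, iterations, seed, lr = 0.01,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  sizes <- c(ncol(X), hidden, 1L)
  par <- mlp_init(sizes, seed)
  L <- length(par$W)
  mW <- lapply(par$W, function(w) w * 0); vW <- mW
  mb <- lapply(par$b, function(b) b * 0); vb <- mb
  n <- nrow(X)
  for (step in seq_len(iterations)) {
    acts <- mlp_forward(par, X)
    delta <- (acts[[L + 1]] - y) * (2 / n)   # d(MSE)/d(output)
    for (l in rev(seq_len(L))) {
      gW <- crossprod(acts[[l]], delta)
      gb <- colSums(delta)
      if (l > 1) {
        delta <- (delta %*% t(par$W[[l]])) * (acts[[l]] > 0)
      }
      mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
      vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
      mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
      vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
      corr1 <- 1 - beta1^step
      corr2 <- 1 - beta2^step
      par$W[[l]] <- par$W[[l]] - lr * (mW[[l]] / corr1) /
        (sqrt(vW[[l]] / corr2) + eps)
      par$b[[l]] <- par$b[[l]] - lr * (mb[[l]] / corr1) /
        (sqrt(vb[[l]] / corr2) + eps)
    }
  }
  par
}
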