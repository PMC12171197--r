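test_that("splits partition the table deterministically", {
  tab <- simulate_sample_table(100, sim_config(n_bands = 20, seed = 19), seed = 19)
  s1 <- split_table(tab, 0.3, seed = 2)
  s2 <- split_table(tab, 0.3, seed = 2)
  expect_equal(nrow(s1$calibration$reflectance), 70)
  expect_equal(nrow(s1$prediction$reflectance), 30)
  expect_identical(s1$prediction$sample_ids, s2$prediction$sample_ids)
  expect_setequal(c(s1$calibration$sample_ids, s1$prediction$sample_ids),
                  tab$sample_ids)
  expect_length(intersect(s1$calibration$sample_ids,
                          s1$prediction$sample_ids), 0)
  st <- split_table(tab, 0.3, method = "stratified", seed = 2)
  expect_setequal(c(st$calibration$sample_ids, st$prediction$sample_ids),
                  tab$sample_ids)
  expect_error(split_table(tab, 1.2), "test_fraction")
})

test_that("MLR recovers exact linear coefficients and names collinear columns", {
  set.seed(20)
  X <- matrix(rnorm(60 * 8), 60, 8)
  beta <- rnorm(8)
  y <- drop(X %*% beta) + 2
  m <- fit_regressor(regressor_spec("MLR"), X, y)
  expect_lt(max(abs(predict(m, X) - y)), 1e-8)
  Xs <- cbind(X, X[, 1] + X[, 2])
  expect_error(fit_regressor(regressor_spec("MLR"), Xs, y), "collinear")
})

test_that("PLSR with full components equals MLR on full-rank designs", {
  set.seed(21)
  X <- matrix(rnorm(50 * 6), 50, 6)
  y <- rnorm(50)
  mp <- fit_regressor(regressor_spec("PLSR", n_components = 6), X, y)
  ml <- fit_regressor(regressor_spec("MLR"), X, y)
  expect_equal(predict(mp, X), predict(ml, X), tolerance = 1e-8)
})

test_that("RF and ANN are deterministic under their seeds", {
  set.seed(22)
  X <- matrix(rnorm(80 * 10), 80, 10)
  y <- drop(X %*% rnorm(10))
  for (kind in c("RF", "ANN")) {
    m1 <- fit_regressor(regressor_spec(kind), X, y)
    m2 <- fit_regressor(regressor_spec(kind), X, y)
    expect_identical(predict(m1, X), predict(m2, X))
  }
  m3 <- fit_regressor(regressor_spec("RF", rf_seed = 43L), X, y)
  m1 <- fit_regressor(regressor_spec("RF"), X, y)
  expect_false(identical(predict(m1, X), predict(m3, X)))
})

test_that("the ANN learns a smooth nonlinear response", {
  set.seed(23)
  X <- matrix(runif(200 * 3, -1, 1), 200, 3)
  y <- sin(2 * X[, 1]) + X[, 2]^2 - 0.5 * X[, 3]
  m <- fit_regressor(regressor_spec("ANN"), X, y)
  expect_gt(r_squared(y, predict(m, X)), 0.95)
})

test_that("k-fold CV pools out-of-fold predictions with balanced folds", {
  set.seed(24)
  X <- matrix(rnorm(45 * 4), 45, 4)
  y <- drop(X %*% c(1, -1, 0.5, 2)) + 0.3
  cv <- kfold_cv(regressor_spec("MLR"), X, y, k = 10, seed = 6)
  expect_lt(cv$rmsecv, 1e-8)   # noiseless linear data
  # brute-force per-fold recomputation with the same fold assignment
  folds <- hyperleaf:::with_seed(6, sample(rep(1:10, length.out = 45)))
  expect_true(all(abs(table(folds) - 4.5) <= 0.5))
  y2 <- y + rnorm(45, 0, 0.1)
  cv2 <- kfold_cv(regressor_spec("MLR"), X, y2, k = 10, seed = 6)
  pred <- numeric(45)
  for (f in 1:10) {
    test <- folds == f
    cf <- qr.coef(qr(cbind(1, X[!test, ])), y2[!test])
    pred[test] <- drop(cbind(1, X[test, ]) %*% cf)
  }
  expect_equal(cv2$rmsecv, sqrt(mean((y2 - pred)^2)), tolerance = 1e-10)
  expect_error(kfold_cv(regressor_spec("MLR"), X, y, k = 1), "k must be")
})

test_that("evaluation metrics follow their definitions", {
  obs <- c(0.2, 0.4, 0.6, 0.8)
  expect_equal(r_squared(obs, obs), 1)
  expect_equal(rmse(obs, obs), 0)
  expect_equal(r_squared(obs, rep(mean(obs), 4)), 0)
  set.seed(25)
  pred <- obs + rnorm(4, 0, 0.05)
  expect_equal(r_squared(obs, pred),
               1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2),
               tolerance = 1e-12)
  expect_equal(rmse(obs, pred), sqrt(mean((obs - pred)^2)), tolerance = 1e-12)
  expect_error(r_squared(rep(1, 4), pred), "zero variance")
})

test_that("calibration R^2 is at least the cross-validated R^2 for MLR", {
  set.seed(26)
  X <- matrix(rnorm(60 * 5), 60, 5)
  y <- drop(X %*% rnorm(5)) + rnorm(60, 0, 0.5)
  m <- fit_regressor(regressor_spec("MLR"), X, y)
  cal <- evaluate(m, X, y)
  cv <- kfold_cv(regressor_spec("MLR"), X, y, k = 10, seed = 3)
  expect_gte(cal$r2, cv$r2_cv)
})
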