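test_that("lasso reduces to OLS at lambda = 0 and soft-thresholds when orthonormal", {
  n <- 64; p <- 8
  D <- orthonormal_design(n, p, seed = 10)
  set.seed(10)
  beta <- c(3, -2, 1.5, 0.8, 0.4, 0, 0, 0)
  y <- drop(D %*% beta) + rnorm(n, sd = 0.3)
  yc <- y - mean(y)
  ols <- drop(crossprod(D, yc)) / n   # orthonormal: OLS = correlations

  f0 <- fit_lasso(D, y, lambda = 0, family = "continuous")
  ref <- qr.coef(qr(cbind(1, D)), y)
  expect_equal(f0$coefficients, unname(ref[-1]), tolerance = 1e-10)

  lam <- 0.5
  fl <- fit_lasso(D, y, lambda = lam, family = "continuous",
                  standardize = FALSE, intercept = FALSE)
  ols_nc <- drop(crossprod(D, y)) / n
  soft <- sign(ols_nc) * pmax(abs(ols_nc) - lam, 0)
  expect_equal(fl$coefficients, soft, tolerance = 1e-5)

  # full shrinkage at large lambda
  fbig <- fit_lasso(D, y, lambda = 100, family = "continuous")
  expect_identical(fbig$coefficients, rep(0, p))

  # unpenalized columns are never shrunk to zero by a large penalty
  fu <- fit_lasso(D, y, lambda = 100, family = "continuous",
                  unpenalized_mask = c(TRUE, rep(FALSE, p - 1)))
  expect_gt(abs(fu$coefficients[1]), 1)
  expect_identical(fu$coefficients[-1], rep(0, p - 1))

  expect_error(fit_lasso(D, rep(1, n)), "constant")
})

test_that("nodewise lasso returns the column itself when columns are orthogonal", {
  D <- orthonormal_design(60, 5, seed = 11)
  nw <- nodewise_lasso(D, 2, lambda_j = 0.2, intercept = FALSE)
  expect_equal(nw$gamma, rep(0, 4), tolerance = 1e-8)
  expect_equal(nw$zj, D[, 2], tolerance = 1e-8)
  expect_equal(nw$tau2, mean(D[, 2]^2), tolerance = 1e-8)

  # perfectly collinear columns are a degeneracy error on the exact path
  set.seed(12)
  x <- rnorm(50)
  D2 <- cbind(x, x, rnorm(50))
  expect_error(nodewise_lasso(D2, 1, lambda_j = 0), "degenerate")
})

test_that("nodewise residuals nearly orthogonalize an AR(1) design", {
  set.seed(13)
  n <- 500; p <- 20
  L <- chol(ar1_covariance(p, 0.8))
  D <- matrix(rnorm(n * p), n, p) %*% L
  D <- scale(D)
  nw <- nodewise_lasso(D, 10, lambda_j = 0.01, intercept = FALSE)
  ratios <- drop(crossprod(D, nw$zj)) / sum(nw$zj * D[, 10])
  expect_true(all(abs(ratios[-10]) < 0.05))
})

test_that("scaled lasso recovers the noise scale and is scale-equivariant", {
  set.seed(14)
  n <- 2000; p <- 50
  D <- matrix(rnorm(n * p), n, p)
  y <- rnorm(n)                       # pure noise, sigma = 1
  sl <- scaled_lasso_sigma(D, y)
  expect_lt(abs(sl$sigma_eps - 1), 0.1)

  sl2 <- scaled_lasso_sigma(D, 2 * y)
  expect_equal(sl2$sigma_eps, 2 * sl$sigma_eps, tolerance = 1e-6)

  # noiseless linear response: estimated scale collapses toward zero
  set.seed(15)
  Dn <- matrix(rnorm(300 * 5), 300, 5)
  y0 <- drop(Dn %*% c(1, -1, 0.5, 0, 0))
  sl0 <- scaled_lasso_sigma(Dn, y0)
  expect_lt(sl0$sigma_eps, 0.1)
  expect_lt(sl0$sigma_eps / sd(y0), 0.05)
})
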