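test_that("linear de-biasing reduces exactly to OLS in the unpenalized regime", {
  set.seed(31)
  n <- 200; p <- 20
  D <- matrix(rnorm(n * p), n, p) %*% chol(ar1_covariance(p, 0.5))
  beta <- c(rep(1, 5), rep(0, p - 5))
  y <- 2 + drop(D %*% beta) + rnorm(n)
  fit <- debias_linear(D, y, lambda = 0, nodewise_lambdas = 0)
  ols <- lm(y ~ D)
  expect_equal(fit$estimates, unname(coef(ols)[-1]), tolerance = 1e-8)
  # standard errors equal the OLS formula with the scaled-lasso sigma
  se_ols <- unname(coef(summary(ols))[-1, "Std. Error"])
  sigma_ols <- summary(ols)$sigma
  expect_equal(fit$se, se_ols * fit$sigma_eps / sigma_ols, tolerance = 1e-6)
})

test_that("single-column de-biasing is the simple regression slope", {
  set.seed(32)
  x <- rnorm(100)
  y <- 1 + 0.7 * x + rnorm(100)
  fit <- debias_linear(cbind(x), y, lambda = 0.01)
  expect_equal(fit$estimates, unname(coef(lm(y ~ x))[2]), tolerance = 1e-6)
})

test_that("de-biasing undoes lasso shrinkage for true signals", {
  # orthonormal design with known coefficients: the lasso soft-thresholds,
  # the corrected estimate recenters near the truth
  set.seed(33)
  n <- 100; p <- 10
  D <- orthonormal_design(n, p, seed = 33)
  beta <- c(1, -1, 0.8, rep(0, p - 3))
  reps <- 100
  err_lasso <- err_debias <- matrix(NA, reps, 3)
  for (r in 1:reps) {
    y <- drop(D %*% beta) + rnorm(n, sd = 0.5)
    fit <- debias_linear(D, y, lambda = 0.15, nodewise_lambdas = 0.05,
                         columns = 1:3)
    err_lasso[r, ] <- fit$lasso_coefficients[1:3] - beta[1:3]
    err_debias[r, ] <- fit$estimates[1:3] - beta[1:3]
  }
  expect_true(all(abs(colMeans(err_debias)) < abs(colMeans(err_lasso))))
  expect_true(all(abs(colMeans(err_debias)) < 0.05))
})

test_that("logistic de-biasing matches the MLE in low dimension", {
  set.seed(34)
  n <- 2000; p <- 3
  D <- matrix(rnorm(n * p), n, p)
  eta <- -0.5 + D %*% c(0.8, -0.5, 0)
  y <- rbinom(n, 1, plogis(eta))
  fit <- debias_logistic(D, y, lambda = 1e-4, nodewise_lambdas = 0)
  ml <- glm(y ~ D, family = binomial())
  mle <- unname(coef(ml)[-1])
  se_w <- unname(coef(summary(ml))[-1, "Std. Error"])
  p_w <- unname(coef(summary(ml))[-1, "Pr(>|z|)"])
  expect_true(all(abs(fit$estimates - mle) < 2 * se_w))
  expect_true(all(abs(fit$pvalues - p_w) < 0.02))
})

test_that("flipping binary labels negates estimates but keeps p-values", {
  set.seed(35)
  n <- 400; p <- 12
  D <- matrix(rnorm(n * p), n, p)
  y <- rbinom(n, 1, plogis(0.3 + drop(D %*% c(1, rep(0, p - 1)))))
  f1 <- debias_logistic(D, y, lambda = 0.02, nodewise_lambdas = 0.05)
  f2 <- debias_logistic(D, 1 - y, lambda = 0.02, nodewise_lambdas = 0.05)
  expect_equal(f2$estimates, -f1$estimates, tolerance = 1e-6)
  expect_equal(f2$pvalues, f1$pvalues, tolerance = 1e-6)
})

test_that("p-values follow the two-sided normal identities", {
  fit <- structure(list(z = c(0, 1.959964, -1.959964, 3)),
                   class = "debiased_fit")
  p <- pvalues_from_fit(fit)
  expect_equal(p[1], 1)
  expect_equal(p[2], 0.05, tolerance = 1e-6)
  expect_identical(p[2], p[3])
  expect_true(all(diff(p[c(1, 2, 4)]) < 0))  # monotone decreasing in |z|
  expect_true(all(p >= 0 & p <= 1))
})
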