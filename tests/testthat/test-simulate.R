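test_that("AR(1) covariance has the stated entries and is positive definite", {
  expect_equal(ar1_covariance(3, 0), diag(3))
  S <- ar1_covariance(2, 0.8)
  expect_equal(S[1, 2], 0.8)
  S3 <- ar1_covariance(3, 0.8)
  expect_equal(S3[1, 3], 0.64)
  expect_equal(S3, t(S3))
  expect_equal(diag(S3), rep(1, 3))
  # Cholesky succeeds well into the high-correlation, high-dimension regime
  expect_no_error(chol(ar1_covariance(2000, 0.95)))
  expect_error(ar1_covariance(3, 1), "rho")
  expect_error(ar1_covariance(3, -0.1), "rho")
})

test_that("exposure draws are Bernoulli(p) and seed-reproducible", {
  set.seed(11)
  x <- generate_exposure(1e4, 0.74)
  expect_true(all(x %in% c(0, 1)))
  expect_lt(abs(mean(x) - 0.74), 3 * sqrt(0.74 * 0.26 / 1e4))
  set.seed(99)
  x1 <- generate_exposure(1e5, 0.74)
  expect_lt(abs(var(x1) - 0.74 * 0.26), 0.005)
  set.seed(5); a <- generate_exposure(5, 0.5)
  set.seed(5); b <- generate_exposure(5, 0.5)
  expect_identical(a, b)
  expect_error(generate_exposure(5, 1), "prob")
})

test_that("mediators have mean theta' + a*X and AR(1) correlation", {
  cfg <- simulation_config(n = 1e4, k = 10, rho = 0,
                           a_vec = rep(0, 10), b_vec = rep(0, 10))
  set.seed(2)
  X <- generate_exposure(cfg$n, cfg$exposure_prob)
  M <- generate_mediators(X, cfg)
  expect_true(all(abs(colMeans(M) - 1) < 0.05))
  cc <- cor(M)
  expect_true(max(abs(cc[upper.tri(cc)])) < 0.05)

  # conditional covariance check: a = 0 so cov(M) is exactly the AR(1) matrix
  cfg8 <- simulation_config(n = 1e4, k = 10, rho = 0.8,
                            a_vec = rep(0, 10), b_vec = rep(0, 10))
  set.seed(13)
  M8 <- generate_mediators(X, cfg8)
  emp <- cov(M8)
  expect_true(max(abs(emp - ar1_covariance(10, 0.8))) < 0.03)

  # all-unexposed: column means reduce to the intercept regardless of a
  M0 <- generate_mediators(rep(0L, 5000), cfg8)
  expect_true(all(abs(colMeans(M0) - 1) < 0.06))
})

test_that("recursive and Cholesky mediator samplers agree in distribution", {
  cfg <- simulation_config(n = 5000, k = 8, rho = 0.7)
  X <- rep(0L, cfg$n)
  set.seed(4); Mr <- generate_mediators(X, cfg, method = "recursive")
  set.seed(4); Mc <- generate_mediators(X, cfg, method = "cholesky")
  expect_lt(max(abs(cov(Mr) - cov(Mc))), 0.08)
  expect_lt(max(abs(colMeans(Mr) - colMeans(Mc))), 0.08)
})

test_that("binary outcome prevalence matches the logistic closed form", {
  k <- 10
  cfg <- simulation_config(n = 1e5, k = k, b_vec = rep(0, k), c_prime = 0)
  set.seed(6)
  X <- generate_exposure(cfg$n, 0.74)
  M <- generate_mediators(X, cfg)
  Y <- generate_outcome(X, M, cfg)
  p0 <- plogis(-4.5)
  expect_lt(abs(mean(Y) - p0), 4 * sqrt(p0 * (1 - p0) / cfg$n))

  # positive b and positive mediator means raise the linear predictor
  cfgs <- simulation_config(n = 1e4, k = k, seed = 7)
  dat <- simulate_mediation(cfgs)
  expect_gt(mean(dat$Y), p0)
})

test_that("true total effect reproduces the design values and is linear", {
  a <- default_a_vec(1000); b <- default_b_vec(1000)
  expect_identical(total_effect_true(a, b, 0), 0.94)
  expect_identical(total_effect_true(a, b, 0.5), 1.44)
  expect_identical(total_effect_true(rep(0, 8), default_b_vec(8), 0.5), 0.5)
  # linearity in each argument
  expect_equal(total_effect_true(2 * a, b, 0), 2 * 0.94)
  expect_equal(total_effect_true(a, 3 * b, 0.25), 0.25 + 3 * 0.94)
  expect_error(total_effect_true(a[1:5], b), "length")
})

test_that("simulated datasets are deterministic and carry correct truth", {
  cfg <- default_cfg(n = 50, k = 20, seed = 123)
  d1 <- simulate_mediation(cfg)
  d2 <- simulate_mediation(cfg)
  expect_identical(d1$X, d2$X)
  expect_identical(d1$M, d2$M)
  expect_identical(d1$Y, d2$Y)
  expect_identical(sum(d1$truth), 4L)
  expect_identical(which(d1$truth), 1:4)
  expect_identical(as.character(d1$truth_class[1:8]),
                   c(rep("mediator", 4), "a_only", "a_only",
                     "b_only", "b_only"))
  expect_true(all(d1$Y %in% c(0, 1)))
  expect_true(all(d1$X %in% c(0, 1)))
})
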