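test_that("screening dimension reproduces the worked values and is monotone", {
  expect_identical(screening_dimension(128), 27L)
  expect_identical(screening_dimension(398, 2), 34L)
  expect_identical(screening_dimension(300), as.integer(ceiling(300 / log(300))))
  ns <- seq(10, 2000, by = 10)
  ds <- vapply(ns, screening_dimension, integer(1))
  expect_true(all(diff(ds) >= 0))
  expect_error(screening_dimension(2), "> e")
  expect_error(screening_dimension(100, 0), "positive")
})

test_that("marginal screen keeps everything when d >= k and ranks by signal", {
  set.seed(21)
  n <- 200; k <- 5
  X <- rbinom(n, 1, 0.5)
  M <- matrix(rnorm(n * k), n, k)
  eta <- -1 + 2 * M[, 3]
  Y <- rbinom(n, 1, plogis(eta))
  scr <- marginal_screen(M, X, Y, d = 10, family = "binary")
  expect_identical(sort(scr$kept), 1:5)
  expect_identical(scr$ranked_indices[1L], 3L)

  # a column tracking the full linear predictor (which no single mediator
  # spans) wins under the gaussian basis
  eta2 <- -1 + 1.2 * M[, 1] + 1.1 * M[, 2]
  Yc <- eta2 + rnorm(n, sd = 0.1)
  M2 <- cbind(M, eta2 + rnorm(n, sd = 0.01))
  scr2 <- marginal_screen(M2, X, Yc, d = 3, family = "continuous")
  expect_identical(scr2$ranked_indices[1L], 6L)
  expect_identical(scr2$kept, scr2$ranked_indices[1:3])
})

test_that("screen is permutation-equivariant and scale-invariant", {
  set.seed(22)
  cfg <- default_cfg(n = 150, k = 30, seed = 31)
  dat <- simulate_mediation(cfg)
  scr <- marginal_screen(dat$M, dat$X, dat$Y, d = 10, family = "binary")
  perm <- sample(30)
  scr_p <- marginal_screen(dat$M[, perm], dat$X, dat$Y, d = 10,
                           family = "binary")
  expect_equal(scr_p$scores, scr$scores[perm], tolerance = 1e-6)
  expect_identical(match(scr_p$kept, order(perm)[scr$kept]) > 0,
                   rep(TRUE, 10))

  # affine rescaling of one column leaves the standardized score unchanged
  M2 <- dat$M
  M2[, 7] <- 100 * M2[, 7] - 3
  scr_s <- marginal_screen(M2, dat$X, dat$Y, d = 10, family = "binary")
  expect_equal(scr_s$scores[7], scr$scores[7], tolerance = 1e-4)
  expect_identical(scr_s$kept, scr$kept)
})

test_that("vectorized logistic screener matches per-column glm fits", {
  set.seed(23)
  cfg <- default_cfg(n = 120, k = 12, seed = 41)
  dat <- simulate_mediation(cfg)
  scr <- marginal_screen(dat$M, dat$X, dat$Y, d = 12, family = "binary")
  ref <- vapply(1:12, function(j) {
    f <- glm(dat$Y ~ dat$X + dat$M[, j], family = binomial())
    unname(abs(coef(summary(f))[3, "z value"]))
  }, numeric(1))
  expect_equal(scr$scores, ref, tolerance = 1e-5)
})

test_that("mediator-model basis scores equal per-column OLS t-statistics", {
  set.seed(24)
  cfg <- default_cfg(n = 100, k = 10, seed = 51)
  dat <- simulate_mediation(cfg)
  scr <- marginal_screen(dat$M, dat$X, dat$Y, d = 10,
                         basis = "mediator_model", family = "binary")
  ref <- vapply(1:10, function(j) {
    unname(abs(coef(summary(lm(dat$M[, j] ~ dat$X)))[2, "t value"]))
  }, numeric(1))
  expect_equal(scr$scores, ref, tolerance = 1e-8)
})

test_that("constant mediator columns score zero with a warning", {
  set.seed(25)
  n <- 80
  X <- rbinom(n, 1, 0.5)
  M <- cbind(rnorm(n), rep(2, n), rnorm(n))
  Y <- rbinom(n, 1, 0.3)
  expect_warning(scr <- marginal_screen(M, X, Y, d = 3, family = "binary"),
                 "constant")
  expect_identical(scr$scores[2], 0)
  expect_identical(scr$ranked_indices[3], 2L)
})
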