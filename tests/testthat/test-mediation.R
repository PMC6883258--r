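test_that("joint p-value is the intersection-union maximum", {
  expect_identical(joint_pvalue(0.01, 0.04), 0.04)
  expect_identical(joint_pvalue(0, 1), 1)
  expect_identical(joint_pvalue(0.3, 0.3), 0.3)
  expect_identical(joint_pvalue(c(0.1, 0.9), c(0.5, 0.2)), c(0.5, 0.9))
  expect_error(joint_pvalue(1.2, 0.5))
})

test_that("effect decomposition reproduces published table rows", {
  # childhood-maltreatment example row: a=0.266, b=1.594, c=1.866
  d1 <- effect_decomposition(0.266, 1.594, 1.866)
  expect_equal(round(d1$ab, 3), 0.424)
  expect_lt(abs(d1$pct_total - 22.748), 0.2)
  # alcohol/EOC example row: a=-0.175, b=-0.878, c=-1.310 (negative total)
  d2 <- effect_decomposition(-0.175, -0.878, -1.310)
  expect_equal(round(d2$ab, 3), 0.154)
  expect_lt(abs(d2$pct_total - 11.709), 0.06)
  # degenerate cases
  d0 <- effect_decomposition(0, 5, 2)
  expect_identical(d0$ab, 0)
  expect_identical(d0$pct_total, 0)
  dz <- effect_decomposition(1, 1, 0)
  expect_identical(dz$ab, 1)
  expect_true(is.na(dz$pct_total))
})

test_that("a-path OLS handles exact fits, nulls and degenerate designs", {
  set.seed(51)
  X <- rbinom(200, 1, 0.6)
  f <- fit_alpha_path(2 * X, X)
  expect_equal(f$a_hat, 2, tolerance = 1e-10)
  expect_lt(f$p_a, 1e-10)
  expect_error(fit_alpha_path(rnorm(10), rep(1, 10)), "constant")

  # null uniformity: p_a over independent mediators passes a KS check
  set.seed(52)
  p <- replicate(400, fit_alpha_path(rnorm(120), rbinom(120, 1, 0.5))$p_a)
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
})

test_that("a-path estimate recovers the design coefficient a1 = 0.35", {
  set.seed(53)
  cfg <- default_cfg(n = 600, k = 8)
  a1 <- replicate(200, {
    cfg$seed <- sample.int(1e6, 1)
    dat <- simulate_mediation(cfg)
    fit_alpha_path(dat$M[, 1], dat$X)$a_hat
  })
  expect_lt(abs(mean(a1) - 0.35), 0.02)
})

test_that("total-effect fit is calibrated and errors on constant exposure", {
  set.seed(54)
  X <- rbinom(500, 1, 0.5)
  Y <- rbinom(500, 1, 0.3)
  f <- fit_total_effect(X, Y, family = "binary")
  expect_true(is.finite(f$c_hat) && f$se > 0)
  expect_error(fit_total_effect(rep(1, 50), rnorm(50), family = "continuous"),
               "constant")
  # null calibration of the continuous fit
  set.seed(55)
  pv <- replicate(400, {
    x <- rbinom(150, 1, 0.5)
    fit_total_effect(x, rnorm(150), family = "continuous")$p
  })
  r <- mean(pv < 0.05)
  expect_gt(r, 0.02); expect_lt(r, 0.09)
})

test_that("hdma_test output satisfies its structural invariants", {
  cfg <- default_cfg(n = 300, k = 60, seed = 61)
  dat <- simulate_mediation(cfg)
  res <- hdma_test(dat$X, dat$M, dat$Y, family = "binary",
                   control = test_control())
  tab <- mediation_table(res)
  tested <- tab$status == "tested"
  expect_identical(sum(tested), res$d)
  # joint p-value dominates both components
  expect_true(all(tab$p_joint[tested] >= tab$p_a[tested] - 1e-12))
  expect_true(all(tab$p_joint[tested] >= tab$p_b[tested] - 1e-12))
  expect_equal(tab$p_joint[tested],
               pmax(tab$p_a[tested], tab$p_b[tested]))
  # significance flag is exactly the intersection rule
  expect_identical(tab$significant,
                   !is.na(tab$p_a) & !is.na(tab$p_b) &
                     tab$p_a < res$alpha & tab$p_b < res$alpha)
  # S-set contains every significant mediator
  expect_true(all(tab$mediator[tab$significant] %in% res$S))
  expect_identical(res$S, sort(tab$mediator[!is.na(tab$p_b) &
                                              tab$p_b < res$alpha]))
  # screened-out mediators are explicitly untested, not p = 1
  expect_true(all(is.na(tab$p_joint[tab$status == "not_retained"])))
  expect_true(all(tab$pct_total_effect >= 0, na.rm = TRUE))
  # decomposition columns recompute from their factors
  expect_equal(tab$ab[tested], tab$a_hat[tested] * tab$b_hat[tested])
  expect_equal(tab$pct_total_effect[tested],
               abs(tab$ab[tested]) / abs(res$c_hat) * 100)
})

test_that("hdma_test is deterministic for a fixed seed and refuses tiny n", {
  cfg <- default_cfg(n = 200, k = 30, seed = 62)
  dat <- simulate_mediation(cfg)
  set.seed(7); r1 <- hdma_test(dat$X, dat$M, dat$Y, family = "binary",
                               control = test_control())
  set.seed(7); r2 <- hdma_test(dat$X, dat$M, dat$Y, family = "binary",
                               control = test_control())
  expect_identical(mediation_table(r1), mediation_table(r2))
  expect_error(hdma_test(dat$X[1:5], dat$M[1:5, ], dat$Y[1:5]), "n < 10")
})

test_that("high-power regime finds all four true mediators", {
  cfg <- simulation_config(n = 1000, k = 8, seed = 63)
  found <- rowMeans(replicate(20, {
    cfg$seed <- cfg$seed + 1
    dat <- simulate_mediation(cfg)
    res <- hdma_test(dat$X, dat$M, dat$Y, family = "binary",
                     control = test_control())
    rejections(res)[1:4]
  }))
  expect_true(all(found >= 0.9))
})

test_that("continuous-family pipeline runs end to end", {
  cfg <- simulation_config(n = 250, k = 40, family = "continuous", seed = 64)
  dat <- simulate_mediation(cfg)
  res <- hdma_test(dat$X, dat$M, dat$Y, family = "continuous",
                   control = test_control())
  expect_s3_class(res, "mediation_result")
  expect_true(is.finite(res$sigma_eps) && res$sigma_eps > 0)
  expect_true(any(rejections(res)[1:4]))
})
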