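# Shared fixtures built in code.

# Small orthonormal-design regression problem: columns scaled so that
# crossprod(D)/n = I, which makes lasso/MCP univariate updates exact
# closed forms.
orthonormal_design <- function(n = 64, p = 8, seed = 1) {
  set.seed(seed)
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(n * p), n, p))))[, -1, drop = FALSE]
  sweep(Q, 2, sqrt(colSums(Q^2) / n), "/")   # mean-square-1 columns, all
                                             # orthogonal to the intercept
}

# Fast harness settings for tests.
test_control <- function(...) harness_control(...)

default_cfg <- function(n = 300, k = 100, rho = 0, seed = 1, ...) {
  simulation_config(n = n, k = k, rho = rho, seed = seed, ...)
}

# temp directory cleaned up with the test process
withr_like_tempdir <- function() {
  d <- tempfile("hdma-test-")
  dir.create(d)
  d
}
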