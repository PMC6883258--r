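#' Default sparse path coefficients
#'
#' The generator's default design places signal on the first eight mediators
#' only: `b = (0.8, 0.7, 0.6, 0.5, 0, 0, 0.5, 0.5)` for the mediator-to-outcome
#' path and `a = (0.35, 0.25, 0.35, 0.55, 0.55, 0.55, 0, 0)` for the
#' exposure-to-mediator path, all remaining entries zero. Under this design
#' mediators 1-4 are true mediators (a_j * b_j != 0), mediators 5-6 carry an
#' a-path only, mediators 7-8 a b-path only, and the rest are complete nulls.
#'
#' @param k total number of mediators (>= 8).
#' @return length-`k` numeric vector.
#' @export
default_a_vec <- function(k) {
  stopifnot(k >= 8)
  c(0.35, 0.25, 0.35, 0.55, 0.55, 0.55, 0, 0, rep(0, k - 8))
}

#' @rdname default_a_vec
#' @export
default_b_vec <- function(k) {
  stopifnot(k >= 8)
  c(0.8, 0.7, 0.6, 0.5, 0, 0, 0.5, 0.5, rep(0, k - 8))
}

#' Simulation configuration
#'
#' Bundles every generative parameter of the synthetic mediation design:
#' a Bernoulli exposure, mediators drawn from a multivariate normal with mean
#' `theta_prime + a_j * X` and AR(1) covariance `Sigma_st = rho^|s-t|`, and an
#' outcome that is either Bernoulli with logistic link
#' `eta = theta2 + c_prime * X + sum_j b_j M_j` or Gaussian around the same
#' linear predictor.
#'
#' @param n sample size (>= 2).
#' @param k number of mediators (>= 8).
#' @param rho AR(1) correlation between adjacent mediators, in `[0, 1)`.
#' @param a_vec length-`k` exposure-to-mediator coefficients; defaults to
#'   [default_a_vec()].
#' @param b_vec length-`k` mediator-to-outcome coefficients; defaults to
#'   [default_b_vec()].
#' @param c_prime direct exposure-to-outcome effect.
#' @param theta2 outcome-model intercept (default -4.5, giving a rare outcome
#'   in the absence of mediator signal).
#' @param theta_prime mediator-model intercept (default 1).
#' @param exposure_prob Bernoulli exposure probability (default 0.74, the
#'   drinking prevalence the design emulates).
#' @param family `"binary"` or `"continuous"` outcome.
#' @param seed optional integer RNG seed stored with the config; when set,
#'   [simulate_mediation()] is fully deterministic.
#' @return object of class `"simulation_config"`.
#' @export
simulation_config <- function(n, k = 100, rho = 0,
                              a_vec = NULL, b_vec = NULL,
                              c_prime = 0, theta2 = -4.5, theta_prime = 1,
                              exposure_prob = 0.74,
                              family = c("binary", "continuous"),
                              seed = NULL) {
  family <- match.arg(family)
  if (!is.numeric(n) || length(n) != 1L || n < 2) {
    stop("`n` must be a single integer >= 2", call. = FALSE)
  }
  if (!is.numeric(k) || length(k) != 1L || k < 8) {
    stop("`k` must be a single integer >= 8", call. = FALSE)
  }
  if (!is.numeric(rho) || length(rho) != 1L || rho < 0 || rho >= 1) {
    stop("`rho` must lie in [0, 1)", call. = FALSE)
  }
  if (exposure_prob <= 0 || exposure_prob >= 1) {
    stop("`exposure_prob` must lie in (0, 1)", call. = FALSE)
  }
  n <- as.integer(n); k <- as.integer(k)
  if (is.null(a_vec)) a_vec <- default_a_vec(k)
  if (is.null(b_vec)) b_vec <- default_b_vec(k)
  if (length(a_vec) != k || length(b_vec) != k) {
    stop("`a_vec` and `b_vec` must have length k = ", k, call. = FALSE)
  }
  structure(
    list(n = n, k = k, rho = rho, a_vec = a_vec, b_vec = b_vec,
         c_prime = c_prime, theta2 = theta2, theta_prime = theta_prime,
         exposure_prob = exposure_prob, family = family,
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "simulation_config"
  )
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("Mediation simulation design\n")
  cat(sprintf("  n = %d, k = %d, rho = %g, family = %s\n",
              x$n, x$k, x$rho, x$family))
  cat(sprintf("  c' = %g, theta2 = %g, theta' = %g, P(X = 1) = %g\n",
              x$c_prime, x$theta2, x$theta_prime, x$exposure_prob))
  tc <- truth_classes(x)
  cat(sprintf("  true mediators: %s\n",
              paste(which(tc == "mediator"), collapse = ", ")))
  invisible(x)
}

#' AR(1) covariance matrix
#'
#' Entry `(s, t)` equals `rho^|s-t|`: unit diagonal, symmetric, and positive
#' definite for `rho` in `[0, 1)`.
#'
#' @param k matrix dimension (>= 1).
#' @param rho AR(1) correlation, in `[0, 1)`.
#' @return `k x k` covariance matrix.
#' @export
ar1_covariance <- function(k, rho) {
  stopifnot(k >= 1)
  if (!is.numeric(rho) || length(rho) != 1L || rho < 0 || rho >= 1) {
    stop("`rho` must lie in [0, 1)", call. = FALSE)
  }
  rho^abs(outer(seq_len(k), seq_len(k), "-"))
}

#' Draw a Bernoulli exposure vector
#'
#' @param n sample size.
#' @param prob success probability, in `(0, 1)`.
#' @return length-`n` 0/1 vector.
#' @export
generate_exposure <- function(n, prob = 0.74) {
  if (prob <= 0 || prob >= 1) stop("`prob` must lie in (0, 1)", call. = FALSE)
  rbinom(n, 1L, prob)
}

#' Draw the mediator matrix
#'
#' Row i is multivariate normal with mean `theta_prime + a * X_i` and AR(1)
#' covariance `rho^|s-t|`. Two exact samplers are provided: a recursive O(nk)
#' AR(1) construction (default, used for large k) and a Cholesky factorisation
#' of the full covariance; they target the identical distribution.
#'
#' @param X length-n 0/1 exposure vector.
#' @param config a [simulation_config()].
#' @param method `"recursive"` or `"cholesky"`.
#' @return `n x k` matrix.
#' @export
generate_mediators <- function(X, config, method = c("recursive", "cholesky")) {
  method <- match.arg(method)
  n <- length(X)
  k <- config$k
  if (!all(X %in% c(0, 1))) stop("`X` must be a 0/1 vector", call. = FALSE)
  rho <- config$rho
  if (method == "recursive") {
    E <- matrix(rnorm(n * k), n, k)
    if (rho > 0) {
      s <- sqrt(1 - rho^2)
      for (j in 2:k) E[, j] <- rho * E[, j - 1L] + s * E[, j]
    }
  } else {
    L <- chol(ar1_covariance(k, rho))
    E <- matrix(rnorm(n * k), n, k) %*% L
  }
  mean_shift <- outer(X, config$a_vec)  # n x k: a_j when exposed, 0 otherwise
  E + config$theta_prime + mean_shift
}

#' Draw the outcome vector
#'
#' Linear predictor `eta_i = theta2 + c_prime * X_i + sum_j b_j M_ij`.
#' Binary family: `Y_i ~ Bernoulli(plogis(eta_i))`. Continuous family:
#' `Y_i = eta_i + N(0, 1)`.
#'
#' @param X exposure vector.
#' @param M mediator matrix.
#' @param config a [simulation_config()].
#' @return length-n outcome vector.
#' @export
generate_outcome <- function(X, M, config) {
  if (length(X) != nrow(M) || ncol(M) != config$k) {
    stop("dimension mismatch between X, M and config", call. = FALSE)
  }
  eta <- config$theta2 + config$c_prime * X + drop(M %*% config$b_vec)
  switch(config$family,
    binary = rbinom(length(eta), 1L, plogis(eta)),
    continuous = eta + rnorm(length(eta)),
    stop("unknown outcome family: ", config$family, call. = FALSE)
  )
}

#' True total effect
#'
#' The total exposure effect decomposes as the direct effect plus the summed
#' per-mediator indirect products: `c = c_prime + sum_j a_j b_j`.
#'
#' @param a_vec,b_vec equal-length coefficient vectors.
#' @param c_prime direct effect.
#' @return scalar total effect.
#' @export
total_effect_true <- function(a_vec, b_vec, c_prime = 0) {
  if (length(a_vec) != length(b_vec)) {
    stop("`a_vec` and `b_vec` must have equal length", call. = FALSE)
  }
  c_prime + sum(a_vec * b_vec)
}

truth_classes <- function(config) {
  a <- config$a_vec != 0
  b <- config$b_vec != 0
  out <- rep("null", config$k)
  out[a & !b] <- "a_only"
  out[!a & b] <- "b_only"
  out[a & b] <- "mediator"
  factor(out, levels = c("mediator", "a_only", "b_only", "null"))
}

#' Simulate one mediation dataset
#'
#' Draws exposure, mediators and outcome under a [simulation_config()] and
#' attaches per-mediator ground truth: `truth` flags mediators with
#' `a_j * b_j != 0`, and `truth_class` distinguishes the two kinds of null
#' (a-path only, b-path only) from complete nulls.
#'
#' @param config a [simulation_config()].
#' @param mediator_sampler passed to [generate_mediators()].
#' @return object of class `"hdma_sim"` with elements `X`, `M`, `Y`, `truth`,
#'   `truth_class`, `config`.
#' @export
simulate_mediation <- function(config,
                               mediator_sampler = c("recursive", "cholesky")) {
  stopifnot(inherits(config, "simulation_config"))
  mediator_sampler <- match.arg(mediator_sampler)
  if (!is.null(config$seed)) set.seed(config$seed)
  X <- generate_exposure(config$n, config$exposure_prob)
  M <- generate_mediators(X, config, method = mediator_sampler)
  colnames(M) <- paste0("M", seq_len(config$k))
  Y <- generate_outcome(X, M, config)
  structure(
    list(X = X, M = M, Y = Y,
         truth = config$a_vec * config$b_vec != 0,
         truth_class = truth_classes(config),
         config = config),
    class = "hdma_sim"
  )
}

#' @export
print.hdma_sim <- function(x, ...) {
  cat(sprintf("Simulated mediation dataset: n = %d, k = %d (%s outcome)\n",
              x$config$n, x$config$k, x$config$family))
  cat(sprintf("  exposed: %d/%d; outcome %s\n",
              sum(x$X), length(x$X),
              if (x$config$family == "binary")
                sprintf("prevalence %.3f", mean(x$Y))
              else sprintf("mean %.3f", mean(x$Y))))
  cat(sprintf("  true mediators: %s\n",
              paste(which(x$truth), collapse = ", ")))
  invisible(x)
}
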