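#' Screening dimension d = n / (divisor * log n)
#'
#' Number of mediators retained by sure independence screening, rounded up.
#' `divisor = 1` gives the usual `n / log(n)`; `divisor = 2` the more
#' conservative `n / (2 log n)` sometimes preferred at larger sample sizes.
#'
#' @param n sample size (must exceed `e` so the log scale is meaningful).
#' @param divisor positive scale factor on the log term.
#' @return integer `ceiling(n / (divisor * log(n)))`.
#' @export
screening_dimension <- function(n, divisor = 1) {
  if (!is.numeric(n) || length(n) != 1L || n <= exp(1)) {
    stop("`n` must be a single number > e", call. = FALSE)
  }
  if (!is.numeric(divisor) || divisor <= 0) {
    stop("`divisor` must be positive", call. = FALSE)
  }
  as.integer(ceiling(n / (divisor * log(n))))
}

#' Marginal screening of mediators
#'
#' Ranks mediators by a standardized marginal association statistic and keeps
#' the top `d`. With `basis = "outcome_model"` each mediator j is scored by
#' `|coef| / se` of `M_j` in the single-mediator outcome regression
#' `Y ~ X + covariates + M_j` (logistic for a binary outcome, least squares
#' otherwise). With `basis = "mediator_model"` the score is `|a_hat_j| / se`
#' from `M_j ~ X + covariates`. Ties are broken by ascending column index.
#'
#' Degenerate columns (constant, or causing a non-convergent / separated
#' logistic fit) score 0 with a warning rather than failing the screen.
#'
#' @param M `n x k` mediator matrix.
#' @param X exposure vector.
#' @param Y outcome vector.
#' @param covariates optional numeric matrix of additional covariates.
#' @param d number of mediators to retain (capped at `k`).
#' @param basis `"outcome_model"` or `"mediator_model"`.
#' @param family `"binary"` or `"continuous"` outcome.
#' @return object of class `"screen_result"`: `ranked_indices`, `scores`,
#'   `kept` (first `min(d, k)` ranked indices), `d`, `basis`.
#' @export
marginal_screen <- function(M, X, Y, covariates = NULL, d,
                            basis = c("outcome_model", "mediator_model"),
                            family = c("binary", "continuous")) {
  basis <- match.arg(basis)
  family <- match.arg(family)
  M <- as.matrix(M)
  n <- nrow(M); k <- ncol(M)
  stopifnot(length(X) == n, length(Y) == n, d >= 1)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    stopifnot(nrow(covariates) == n)
  }
  base <- cbind(`(Intercept)` = 1, X = X, covariates)

  scores <- if (basis == "mediator_model") {
    screen_mediator_model(M, base)
  } else if (family == "continuous") {
    screen_outcome_gaussian(M, base, Y)
  } else if (is.null(covariates)) {
    screen_outcome_binomial_fast(M, X, Y)
  } else {
    screen_outcome_binomial_loop(M, base, Y)
  }

  scores <- unname(scores)
  const <- apply(M, 2L, function(col) var(col) == 0 || !all(is.finite(col)))
  if (any(const)) {
    warning(sum(const), " constant/degenerate mediator column(s) scored 0")
    scores[const] <- 0
  }
  scores[!is.finite(scores)] <- 0

  ranked <- order(scores, seq_len(k), decreasing = c(TRUE, FALSE),
                  method = "radix")
  kept <- ranked[seq_len(min(d, k))]
  structure(
    list(ranked_indices = ranked, scores = scores, kept = kept,
         d = as.integer(min(d, k)), basis = basis),
    class = "screen_result"
  )
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("SIS screen (%s): kept %d of %d mediators\n",
              x$basis, length(x$kept), length(x$scores)))
  cat("  top indices:", paste(head(x$ranked_indices, 10), collapse = ", "),
      "...\n")
  invisible(x)
}

# |a_hat|/se from M_j ~ base, all columns at once via one QR decomposition.
screen_mediator_model <- function(M, base) {
  n <- nrow(M); q <- ncol(base)
  qr_base <- qr(base)
  cf <- qr.coef(qr_base, M)                    # q x k
  res <- qr.resid(qr_base, M)                  # n x k
  s2 <- colSums(res^2) / (n - q)               # residual variance per column
  xtxinv_xx <- chol2inv(qr.R(qr_base))[2L, 2L] # (base'base)^{-1} for X
  se <- sqrt(s2 * xtxinv_xx)
  ifelse(se > 0, abs(cf[2L, ]) / se, 0)
}

# t-statistic of M_j in Y ~ base + M_j, vectorized by residualizing on base.
screen_outcome_gaussian <- function(M, base, Y) {
  n <- nrow(M); q <- ncol(base)
  qr_base <- qr(base)
  ry <- qr.resid(qr_base, Y)
  rm <- qr.resid(qr_base, M)
  mm <- colSums(rm^2)
  my <- drop(crossprod(rm, ry))
  beta <- ifelse(mm > 0, my / mm, 0)
  rss <- sum(ry^2) - beta^2 * mm
  df <- n - q - 1L
  s2 <- pmax(rss, 0) / df
  se <- sqrt(s2 / mm)
  ifelse(is.finite(se) & se > 0, abs(beta) / se, 0)
}

# Fallback: per-mediator logistic fits with covariates.
screen_outcome_binomial_loop <- function(M, base, Y) {
  k <- ncol(M)
  vapply(seq_len(k), function(j) {
    Dj <- cbind(base, M[, j])
    fit <- tryCatch(
      suppressWarnings(glm.fit(Dj, Y, family = binomial())),
      error = function(e) NULL
    )
    if (is.null(fit) || !fit$converged) return(0)
    w <- fit$weights
    A <- crossprod(Dj * sqrt(w))
    v <- tryCatch(solve(A)[ncol(Dj), ncol(Dj)], error = function(e) NA_real_)
    if (!is.finite(v) || v <= 0) return(0)
    abs(fit$coefficients[ncol(Dj)]) / sqrt(v)
  }, numeric(1))
}

# Vectorized IRLS for the k single-mediator logistic regressions
# Y ~ 1 + X + M_j (no extra covariates). All k three-parameter fits are
# iterated simultaneously with closed-form symmetric 3x3 solves.
screen_outcome_binomial_fast <- function(M, X, Y, max_iter = 30L,
                                         tol = 1e-8) {
  n <- nrow(M); k <- ncol(M)
  x2 <- X^2
  B <- matrix(0, 3L, k)            # rows: intercept, X, M_j
  B[1L, ] <- qlogis(pmin(pmax(mean(Y), 1e-3), 1 - 1e-3))
  se3 <- rep(NA_real_, k)
  active <- rep(TRUE, k)
  for (iter in seq_len(max_iter)) {
    eta <- rep(1, n) %o% B[1L, ] + X %o% B[2L, ] + M * rep(B[3L, ], each = n)
    mu <- plogis(eta)
    W <- mu * (1 - mu)
    W <- pmax(W, 1e-10)
    WM <- W * M
    s_w   <- colSums(W)
    s_wx  <- drop(crossprod(W, X))
    s_wx2 <- drop(crossprod(W, x2))
    s_wm  <- colSums(WM)
    s_wxm <- drop(crossprod(WM, X))
    s_wm2 <- colSums(WM * M)
    WZ <- W * eta + (Y - mu)       # W * working response
    g1 <- colSums(WZ)
    g2 <- drop(crossprod(WZ, X))
    g3 <- colSums(WZ * M)
    # symmetric 3x3 solve by cofactors, vectorized over j
    c11 <- s_wx2 * s_wm2 - s_wxm^2
    c12 <- s_wm * s_wxm - s_wx * s_wm2
    c13 <- s_wx * s_wxm - s_wm * s_wx2
    c22 <- s_w * s_wm2 - s_wm^2
    c23 <- s_wm * s_wx - s_w * s_wxm
    c33 <- s_w * s_wx2 - s_wx^2
    det <- s_w * c11 + s_wx * c12 + s_wm * c13
    bad <- !is.finite(det) | abs(det) < 1e-12
    det[bad] <- 1
    b1 <- (c11 * g1 + c12 * g2 + c13 * g3) / det
    b2 <- (c12 * g1 + c22 * g2 + c23 * g3) / det
    b3 <- (c13 * g1 + c23 * g2 + c33 * g3) / det
    delta <- pmax(abs(b1 - B[1L, ]), abs(b2 - B[2L, ]), abs(b3 - B[3L, ]))
    B[1L, ] <- b1; B[2L, ] <- b2; B[3L, ] <- b3
    active <- is.finite(delta) & delta > tol & !bad
    se3 <- sqrt(pmax(c33 / det, 0))
    if (!any(active)) break
  }
  diverged <- !is.finite(B[3L, ]) | abs(B[3L, ]) > 1e3 | !is.finite(se3) |
    se3 == 0
  if (any(diverged)) {
    warning(sum(diverged),
            " mediator column(s) with non-convergent/separated marginal ",
            "logistic fits scored 0")
  }
  sc <- abs(B[3L, ]) / se3
  sc[diverged] <- 0
  sc
}
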