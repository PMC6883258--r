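#' L1-penalized regression fit
#'
#' Thin wrapper around glmnet exposing exactly what the mediation pipeline
#' needs: an L1 penalty on a subset of columns (covariates such as the
#' exposure can be exempted), a fixed penalty level or cross-validated
#' selection, and the unpenalized limit `lambda = 0` computed by ordinary
#' least squares / maximum likelihood for numerical exactness.
#'
#' The objective follows glmnet's scaling: mean squared error / 2 (linear) or
#' mean negative log-likelihood (logistic) plus `lambda * sum(|beta_j|)` over
#' penalized columns.
#'
#' @param design `n x p` numeric matrix.
#' @param response length-n response.
#' @param lambda penalty level; `NULL` selects by `nfolds`-fold CV
#'   (`lambda.min`).
#' @param family `"continuous"` or `"binary"`.
#' @param unpenalized_mask logical length-p vector, `TRUE` for columns exempt
#'   from the penalty (default none).
#' @param nfolds CV folds when `lambda` is `NULL`.
#' @param standardize,intercept passed to glmnet.
#' @return object of class `"lasso_fit"`: `coefficients` (length p),
#'   `intercept`, `lambda`, `family`, `unpenalized_mask`.
#' @export
fit_lasso <- function(design, response, lambda = NULL,
                      family = c("continuous", "binary"),
                      unpenalized_mask = NULL, nfolds = 10,
                      standardize = TRUE, intercept = TRUE) {
  family <- match.arg(family)
  design <- as.matrix(design)
  n <- nrow(design); p <- ncol(design)
  stopifnot(length(response) == n, n >= 2)
  if (var(response) == 0) stop("response is constant; nothing to fit",
                               call. = FALSE)
  if (is.null(unpenalized_mask)) unpenalized_mask <- rep(FALSE, p)
  stopifnot(length(unpenalized_mask) == p)
  glmnet_family <- if (family == "binary") "binomial" else "gaussian"

  if (!is.null(lambda) && length(lambda) == 1L && lambda == 0) {
    cf <- unpenalized_fit(design, response, family, intercept)
    return(structure(list(coefficients = cf$beta, intercept = cf$a0,
                          lambda = 0, family = family,
                          unpenalized_mask = unpenalized_mask),
                     class = "lasso_fit"))
  }

  if (p == 1L) {
    return(fit_lasso_univariate(design, response, lambda, family,
                                unpenalized_mask, standardize, intercept))
  }

  pf <- ifelse(unpenalized_mask, 0, 1)
  if (is.null(lambda)) {
    cv <- glmnet::cv.glmnet(design, response, family = glmnet_family,
                            penalty.factor = pf, nfolds = nfolds,
                            standardize = standardize, intercept = intercept)
    lambda <- cv$lambda.min
    fit <- cv$glmnet.fit
  } else {
    # short warm-start path ending at the requested lambda
    lmax <- max(lambda * 4, lambda + 1e-9)
    path <- exp(seq(log(lmax), log(max(lambda, 1e-9)), length.out = 5))
    fit <- glmnet::glmnet(design, response, family = glmnet_family,
                          penalty.factor = pf, lambda = path,
                          standardize = standardize, intercept = intercept)
  }
  cf <- coef(fit, s = lambda)
  structure(list(coefficients = as.numeric(cf[-1L]),
                 intercept = as.numeric(cf[1L]),
                 lambda = lambda, family = family,
                 unpenalized_mask = unpenalized_mask),
            class = "lasso_fit")
}

# glmnet needs >= 2 columns; the single-column problem has a closed form
# (linear) or a cheap 2-parameter optimization (logistic).
fit_lasso_univariate <- function(design, response, lambda, family,
                                 unpenalized_mask, standardize, intercept) {
  n <- nrow(design)
  x <- design[, 1L]
  sdx <- if (standardize) sd(x) else 1
  if (sdx == 0) stop("constant design column", call. = FALSE)
  xs <- if (standardize) (x - mean(x)) / sdx else x
  if (is.null(lambda)) lambda <- 0.01 * sd(response)
  pen <- if (unpenalized_mask[1L]) 0 else lambda
  if (family == "continuous") {
    yc <- if (intercept) response - mean(response) else response
    xc <- if (intercept) xs - mean(xs) else xs
    b <- soft_threshold(sum(xc * yc) / n, pen) / (sum(xc^2) / n)
    a0 <- if (intercept) mean(response) - b * mean(xs) else 0
  } else {
    obj <- function(par) {
      eta <- (if (intercept) par[1L] else 0) + par[2L] * xs
      mean(log1p(exp(-(2 * response - 1) * eta))) + pen * abs(par[2L])
    }
    opt <- optim(c(0, 0), obj, method = "BFGS")
    b <- opt$par[2L]; a0 <- if (intercept) opt$par[1L] else 0
  }
  structure(list(coefficients = b / sdx,
                 intercept = a0 - (b / sdx) * (if (standardize) mean(x) else 0),
                 lambda = lambda, family = family,
                 unpenalized_mask = unpenalized_mask),
            class = "lasso_fit")
}

unpenalized_fit <- function(design, response, family, intercept) {
  D <- if (intercept) cbind(1, design) else design
  if (family == "continuous") {
    cf <- qr.coef(qr(D), response)
  } else {
    fit <- suppressWarnings(glm.fit(D, response, family = binomial()))
    if (!fit$converged) stop("unpenalized logistic fit did not converge ",
                             "(possible separation)", call. = FALSE)
    cf <- fit$coefficients
  }
  cf[is.na(cf)] <- 0
  if (intercept) list(a0 = cf[1L], beta = unname(cf[-1L]))
  else list(a0 = 0, beta = unname(cf))
}

#' Nodewise lasso regression of one column on the others
#'
#' Regresses design column `j` on the remaining columns with an L1 penalty and
#' stores the residual `Z_j = M_j - M_{-j} gamma_hat`, the projection
#' direction used by the de-sparsified lasso. Errors if `Z_j' M_j` is
#' numerically zero (e.g. perfectly collinear columns at `lambda = 0`), since
#' the de-biasing formula divides by it.
#'
#' @param design `n x p` matrix, `p >= 2`.
#' @param j target column index.
#' @param lambda_j penalty; `NULL` selects by cross-validation, `0` gives the
#'   least-squares residual.
#' @param nfolds,nlambda CV settings when `lambda_j` is `NULL`.
#' @param intercept include an (unpenalized) intercept in the nodewise
#'   regression.
#' @return list with `j`, `gamma` (length p-1), `zj` (length n), `tau2`
#'   (`mean(zj^2) + lambda_j * sum(|gamma|)`), `lambda`.
#' @export
nodewise_lasso <- function(design, j, lambda_j = NULL, nfolds = 10,
                           nlambda = 100, intercept = TRUE) {
  design <- as.matrix(design)
  p <- ncol(design); n <- nrow(design)
  stopifnot(p >= 2, j >= 1, j <= p)
  mj <- design[, j]
  Mmj <- design[, -j, drop = FALSE]
  if (!is.null(lambda_j) && lambda_j == 0) {
    D <- if (intercept) cbind(1, Mmj) else Mmj
    qrD <- qr(D)
    gamma <- qr.coef(qrD, mj)
    gamma[is.na(gamma)] <- 0
    zj <- mj - drop(D %*% gamma)
    gamma <- if (intercept) unname(gamma[-1L]) else unname(gamma)
    lambda_j <- 0
  } else if (is.null(lambda_j)) {
    cv <- glmnet::cv.glmnet(Mmj, mj, nfolds = nfolds, nlambda = nlambda,
                            standardize = FALSE, intercept = intercept)
    lambda_j <- cv$lambda.min
    zj <- mj - drop(predict(cv$glmnet.fit, Mmj, s = lambda_j))
    gamma <- as.numeric(coef(cv$glmnet.fit, s = lambda_j))[-1L]
  } else {
    lmax <- max(abs(crossprod(Mmj, mj - mean(mj) * intercept))) / n
    lmax <- max(lmax, lambda_j * 1.001)
    path <- exp(seq(log(lmax), log(lambda_j), length.out = 5))
    fit <- glmnet::glmnet(Mmj, mj, lambda = path, standardize = FALSE,
                          intercept = intercept)
    zj <- mj - drop(predict(fit, Mmj, s = lambda_j))
    gamma <- as.numeric(coef(fit, s = lambda_j))[-1L]
  }
  ztm <- sum(zj * mj)
  if (!is.finite(ztm) || abs(ztm) < 1e-8 * n) {
    stop("nodewise regression degenerate for column ", j,
         ": Z_j' M_j is numerically zero (collinear column?)", call. = FALSE)
  }
  list(j = j, gamma = gamma, zj = zj,
       tau2 = mean(zj^2) + lambda_j * sum(abs(gamma)),
       lambda = lambda_j)
}

# Nodewise residuals for many target columns of an already-prepared matrix
# (no intercept, columns on a common scale). mode: "cv" per-column CV,
# "shared" CV on probe columns with the geometric-mean lambda applied
# everywhere, or a fixed numeric lambda.
nodewise_residuals <- function(Mstd, targets, control) {
  p <- ncol(Mstd)
  mode <- control$nodewise_lambda
  if (is.numeric(mode)) {
    lam <- rep(mode, length(targets))
  } else if (mode == "shared") {
    probes <- targets[unique(pmax(1L, round(seq(1, length(targets),
                                length.out = min(control$nodewise_probes,
                                                 length(targets))))))]
    lams <- vapply(probes, function(j) {
      cv <- glmnet::cv.glmnet(Mstd[, -j, drop = FALSE], Mstd[, j],
                              nfolds = control$nodewise_nfolds,
                              nlambda = control$nodewise_nlambda,
                              standardize = FALSE, intercept = FALSE)
      cv$lambda.min
    }, numeric(1))
    lam <- rep(exp(mean(log(lams))), length(targets))
  } else {
    lam <- rep(NA_real_, length(targets))  # per-column CV below
  }
  out <- vector("list", length(targets))
  for (i in seq_along(targets)) {
    j <- targets[i]
    if (is.na(lam[i])) {
      nw <- nodewise_lasso(Mstd, j, lambda_j = NULL,
                           nfolds = control$nodewise_nfolds,
                           nlambda = control$nodewise_nlambda,
                           intercept = FALSE)
    } else {
      nw <- nodewise_lasso(Mstd, j, lambda_j = lam[i], intercept = FALSE)
    }
    out[[i]] <- nw
  }
  out
}

#' Scaled-lasso estimate of the noise level
#'
#' Alternates the lasso coefficient update and the noise-scale update
#' `sigma^2 = ||y - X beta||^2 / n` with penalty `lambda = sigma * lam0`,
#' until the scale converges (Sun-Zhang scaled lasso). Columns are centered
#' and scaled internally; the response is centered.
#'
#' @param design `n x p` matrix.
#' @param response length-n numeric response (linear model).
#' @param lam0 base penalty; default `sqrt(2 * log(p) / n)`.
#' @param max_iter maximum alternations.
#' @param tol relative convergence tolerance on sigma.
#' @return list with `sigma_eps`, `coefficients` (original scale),
#'   `lambda` (final penalty), `iterations`.
#' @export
scaled_lasso_sigma <- function(design, response, lam0 = NULL,
                               max_iter = 50, tol = 1e-4) {
  design <- as.matrix(design)
  n <- nrow(design); p <- ncol(design)
  stopifnot(length(response) == n, n >= 2)
  yc <- response - mean(response)
  sds <- apply(design, 2L, sd)
  sds[sds == 0] <- 1
  Mstd <- scale(design, center = TRUE, scale = sds)
  if (is.null(lam0)) lam0 <- sqrt(2 * log(max(p, 2)) / n)

  sigma <- sd(yc)
  if (sigma == 0) {
    return(list(sigma_eps = 0, coefficients = rep(0, p), lambda = 0,
                iterations = 0L))
  }
  if (p == 1L) {
    # univariate closed form: soft-threshold of the standardized covariance
    for (it in seq_len(max_iter)) {
      lambda <- sigma * lam0
      bz <- soft_threshold(sum(Mstd[, 1] * yc) / n, lambda) /
        (sum(Mstd[, 1]^2) / n)
      r <- yc - Mstd[, 1] * bz
      sigma_new <- sqrt(mean(r^2))
      if (abs(sigma_new - sigma) < tol * max(sigma, 1e-12)) break
      sigma <- sigma_new
    }
    return(list(sigma_eps = sigma_new, coefficients = bz / sds,
                lambda = lambda, iterations = it))
  }
  path <- glmnet::glmnet(Mstd, yc, standardize = FALSE, intercept = FALSE)
  beta <- rep(0, p)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    lambda <- sigma * lam0
    beta <- as.numeric(coef(path, s = lambda))[-1L]
    r <- yc - drop(Mstd %*% beta)
    sigma_new <- sqrt(mean(r^2))
    converged <- abs(sigma_new - sigma) < tol * max(sigma, 1e-12)
    sigma <- sigma_new
    if (converged) break
  }
  if (!converged) {
    stop("scaled lasso did not converge in ", max_iter, " alternations",
         call. = FALSE)
  }
  list(sigma_eps = sigma, coefficients = beta / sds, lambda = lambda,
       iterations = it)
}

soft_threshold <- function(z, lambda) sign(z) * pmax(abs(z) - lambda, 0)
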