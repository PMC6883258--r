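#' De-sparsified lasso inference, linear outcome model
#'
#' Bias-corrects the lasso fit of `response ~ design` column by column using
#' nodewise-lasso residuals:
#' `b_hat_j = Z_j'Y / Z_j'M_j - sum_{l != j} (Z_j'M_l / Z_j'M_j) b_lasso_l`,
#' with standard error `sigma_eps * ||Z_j||_2 / |Z_j'M_j|` (noise scale from
#' the scaled lasso) and two-sided normal p-values. In the unpenalized,
#' well-conditioned limit (`lambda = 0`, `nodewise_lambdas = 0`) the estimator
#' reduces exactly to ordinary least squares.
#'
#' Columns are centered and scaled to unit standard deviation internally;
#' estimates and standard errors are reported on the original scale.
#'
#' @param design `n x p` numeric matrix (mediators plus any covariates).
#' @param response length-n numeric response.
#' @param unpenalized integer indices of columns exempt from the lasso
#'   penalty (e.g. the exposure); they still participate in the nodewise
#'   regressions.
#' @param lambda coefficient-lasso penalty; `NULL` = cross-validated.
#' @param nodewise_lambdas overrides the nodewise penalty policy in
#'   `control`: a single numeric applied to every column, or `0` for
#'   least-squares residuals.
#' @param columns which columns to de-bias and report (default all); the
#'   correction term always uses the full lasso fit.
#' @param control an [hdma_control()].
#' @return object of class `"debiased_fit"`: `estimates`, `se`, `z`,
#'   `pvalues` (aligned with `columns`), `sigma_eps`, `lasso_coefficients`
#'   (full length-p vector, original scale), `lambda`, `columns`, `family`.
#' @export
debias_linear <- function(design, response, unpenalized = integer(0),
                          lambda = NULL, nodewise_lambdas = NULL,
                          columns = NULL, control = hdma_control()) {
  design <- as.matrix(design)
  n <- nrow(design); p <- ncol(design)
  stopifnot(length(response) == n)
  if (is.null(columns)) columns <- seq_len(p)
  yc <- response - mean(response)
  sds <- apply(design, 2L, sd)
  if (any(sds == 0)) stop("constant design column(s): ",
                          paste(which(sds == 0), collapse = ", "),
                          call. = FALSE)
  Mstd <- scale(design, center = TRUE, scale = sds)

  mask <- rep(FALSE, p); mask[unpenalized] <- TRUE
  if (is.null(lambda)) lambda <- control$lambda
  lasso <- fit_lasso(Mstd, yc, lambda = lambda, family = "continuous",
                     unpenalized_mask = mask, nfolds = control$lasso_nfolds,
                     standardize = FALSE, intercept = FALSE)
  blasso <- lasso$coefficients

  sl <- scaled_lasso_sigma(design, response)
  sigma_eps <- sl$sigma_eps

  ctrl <- control
  if (!is.null(nodewise_lambdas)) ctrl$nodewise_lambda <- nodewise_lambdas
  nw <- if (p >= 2) nodewise_residuals(Mstd, columns, ctrl) else
    lapply(columns, function(j) list(j = j, zj = Mstd[, j],
                                     gamma = numeric(0), lambda = 0,
                                     tau2 = mean(Mstd[, j]^2)))

  est <- se <- numeric(length(columns))
  for (i in seq_along(columns)) {
    j <- columns[i]
    zj <- nw[[i]]$zj
    ztm <- drop(crossprod(Mstd, zj))   # Z_j' M_l for all l
    num <- sum(zj * yc) - sum(ztm[-j] * blasso[-j])
    est[i] <- num / ztm[j]
    se[i] <- sigma_eps * sqrt(sum(zj^2)) / abs(ztm[j])
  }
  z <- est / se
  new_debiased_fit(
    estimates = est / sds[columns], se = se / sds[columns], z = z,
    sigma_eps = sigma_eps, lasso_coefficients = blasso / sds,
    lambda = lasso$lambda, columns = columns, family = "continuous",
    nodewise = nw
  )
}

#' De-sparsified lasso inference, logistic outcome model
#'
#' Implements the generalized-linear-model de-biasing scheme: fit the logistic
#' lasso, weight the design (including the intercept column) by the square
#' root of the fitted variances `mu(1-mu)`, run nodewise lasso regressions on
#' the weighted design to build rows of the approximate inverse information
#' `Theta_hat`, and correct `beta_tilde = beta_hat - Theta_hat * gradient`
#' where the gradient is of the average negative log-likelihood at
#' `beta_hat`. Per-coefficient scales default to the weighted-design
#' (Fisher) covariance `sigma_j^2 = (Theta_hat Sigma_hat Theta_hat')_jj`
#' used by the reference nodewise algorithm; the empirical
#' score-outer-product sandwich is available via
#' `control$glm_variance = "sandwich"`. P-values are
#' `P_j = 2(1 - Phi(sqrt(n) |beta_tilde_j| / sigma_j))`.
#'
#' @inheritParams debias_linear
#' @param columns indices of `design` columns to de-bias and report.
#' @return object of class `"debiased_fit"` (no `sigma_eps` for the logistic
#'   family).
#' @export
debias_logistic <- function(design, response, unpenalized = integer(0),
                            lambda = NULL, nodewise_lambdas = NULL,
                            columns = NULL, control = hdma_control()) {
  design <- as.matrix(design)
  n <- nrow(design); p <- ncol(design)
  stopifnot(length(response) == n, all(response %in% c(0, 1)))
  if (is.null(columns)) columns <- seq_len(p)
  sds <- apply(design, 2L, sd)
  if (any(sds == 0)) stop("constant design column(s): ",
                          paste(which(sds == 0), collapse = ", "),
                          call. = FALSE)
  Mstd <- scale(design, center = TRUE, scale = sds)

  mask <- rep(FALSE, p); mask[unpenalized] <- TRUE
  if (is.null(lambda)) lambda <- control$lambda
  lasso <- fit_lasso(Mstd, response, lambda = lambda, family = "binary",
                     unpenalized_mask = mask, nfolds = control$lasso_nfolds,
                     standardize = FALSE, intercept = TRUE)
  beta_full <- c(lasso$intercept, lasso$coefficients)  # on A = [1, Mstd]

  A <- cbind(1, Mstd)
  eta <- drop(A %*% beta_full)
  mu <- plogis(eta)
  if (all(mu > 0.999) || all(mu < 0.001)) {
    stop("fitted probabilities degenerate (possible complete separation)",
         call. = FALSE)
  }
  w <- pmax(mu * (1 - mu), control$weight_floor)
  Aw <- A * sqrt(w)

  grad <- -drop(crossprod(A, response - mu)) / n  # d/dbeta of avg neg loglik

  ctrl <- control
  if (!is.null(nodewise_lambdas)) ctrl$nodewise_lambda <- nodewise_lambdas
  targets <- columns + 1L                         # offset for intercept col
  nw <- nodewise_residuals(Aw, targets, ctrl)

  est <- se <- numeric(length(columns))
  resid <- response - mu
  for (i in seq_along(columns)) {
    jA <- targets[i]
    g <- nw[[i]]$gamma
    tau2 <- nw[[i]]$tau2
    theta <- numeric(p + 1L)
    theta[jA] <- 1
    theta[-jA] <- -g
    theta <- theta / tau2
    bt <- beta_full[jA] - sum(theta * grad)
    v <- drop(A %*% theta)
    sigma2_j <- if (identical(control$glm_variance, "sandwich")) {
      mean((v * resid)^2)        # empirical score outer product
    } else {
      mean(v^2 * w)              # weighted-design (Fisher) form
    }
    est[i] <- bt
    se[i] <- sqrt(sigma2_j / n)
  }
  z <- est / se
  new_debiased_fit(
    estimates = est / sds[columns], se = se / sds[columns], z = z,
    sigma_eps = NULL, lasso_coefficients = lasso$coefficients / sds,
    lambda = lasso$lambda, columns = columns, family = "binary",
    nodewise = nw
  )
}

new_debiased_fit <- function(estimates, se, z, sigma_eps, lasso_coefficients,
                             lambda, columns, family, nodewise) {
  estimates <- unname(estimates); se <- unname(se); z <- unname(z)
  structure(
    list(estimates = estimates, se = se, z = z,
         pvalues = pmin(pmax(2 * pnorm(-abs(z)), 0), 1),
         sigma_eps = sigma_eps,
         lasso_coefficients = lasso_coefficients,
         lambda = lambda, columns = columns, family = family,
         nodewise = nodewise),
    class = "debiased_fit"
  )
}

#' @export
print.debiased_fit <- function(x, ...) {
  cat(sprintf("De-sparsified lasso fit (%s family): %d coefficient(s)\n",
              x$family, length(x$estimates)))
  if (!is.null(x$sigma_eps)) {
    cat(sprintf("  scaled-lasso sigma_eps = %.4f\n", x$sigma_eps))
  }
  cat(sprintf("  lasso lambda = %.5f\n", x$lambda))
  df <- data.frame(column = x$columns, estimate = x$estimates, se = x$se,
                   z = x$z, p = x$pvalues)
  print(head(df, 10), row.names = FALSE, digits = 4)
  if (nrow(df) > 10) cat("  ...", nrow(df) - 10, "more rows\n")
  invisible(x)
}

#' Two-sided normal p-values from a de-biased fit
#'
#' `P_j = 2(1 - Phi(|z_j|))`, clamped to `[0, 1]`.
#'
#' @param fit a `"debiased_fit"`.
#' @return numeric vector of p-values aligned with `fit$columns`.
#' @export
pvalues_from_fit <- function(fit) {
  stopifnot(inherits(fit, "debiased_fit"))
  pmin(pmax(2 * pnorm(-abs(fit$z)), 0), 1)
}
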