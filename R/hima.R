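#' Mediation testing by MCP selection and refit (HIMA comparator)
#'
#' The selection-plus-refit strategy the de-sparsified pipeline is compared
#' against: after the shared SIS step, mediators are selected by an
#' MCP-penalized outcome regression (BIC-tuned penalty, exposure and
#' covariates unpenalized), the survivors are refitted in an ordinary
#' (unpenalized) outcome model whose Wald tests give `p_b`, and the same
#' intersection-union rule `max(p_a, p_b) < alpha` declares mediation.
#' Refit p-values ignore the selection step; that post-selection optimism is
#' a documented property of the comparator, not corrected here.
#'
#' @inheritParams hdma_test
#' @return object of class `"mediation_result"`; mediators the penalty
#'   dropped have status `"not_selected"`.
#' @export
hima_test <- function(X, M, Y, covariates = NULL,
                      family = c("binary", "continuous"),
                      control = hdma_control()) {
  family <- match.arg(family)
  M <- as.matrix(M)
  n <- nrow(M); k <- ncol(M)
  if (n < 10) stop("refusing to run with n < 10 samples", call. = FALSE)
  stopifnot(length(X) == n, length(Y) == n)
  if (is.null(colnames(M))) colnames(M) <- paste0("M", seq_len(k))

  log_stage(control, "screening %d mediators (n = %d)", k, n)
  d <- screening_dimension(n, control$sis_divisor)
  scr <- marginal_screen(M, X, Y, covariates, d = d,
                         basis = resolve_sis_basis(control, family),
                         family = family)
  kept <- scr$kept

  log_stage(control, "MCP selection over %d retained mediators", length(kept))
  q <- if (is.null(covariates)) 0L else ncol(as.matrix(covariates))
  design <- cbind(X = X, covariates, M[, kept, drop = FALSE])
  mask <- c(rep(TRUE, 1L + q), rep(FALSE, length(kept)))
  mcp <- fit_mcp(design, Y, gamma = control$mcp_gamma,
                 family = if (family == "binary") "binary" else "continuous",
                 unpenalized_mask = mask, nlambda = control$mcp_nlambda,
                 lambda_min_ratio = control$mcp_lambda_min_ratio)
  surv_local <- mcp$selected - (1L + q)      # positions within `kept`
  survivors <- kept[surv_local]

  b_hat <- se_b <- p_b <- rep(NA_real_, length(kept))
  c_prime_hat <- NA_real_
  if (length(survivors) > 0) {
    log_stage(control, "refitting %d MCP survivors", length(survivors))
    D <- cbind(1, X, covariates, M[, survivors, drop = FALSE])
    med_pos <- seq.int(3L + q, length.out = length(survivors))
    if (family == "binary") {
      fit <- suppressWarnings(glm.fit(D, Y, family = binomial()))
      if (!fit$converged) stop("refit logistic model did not converge",
                               call. = FALSE)
      cf <- fit$coefficients
      cov <- chol2inv(chol(crossprod(D * sqrt(fit$weights))))
    } else {
      qrD <- qr(D)
      cf <- qr.coef(qrD, Y)
      res <- qr.resid(qrD, Y)
      cov <- chol2inv(qr.R(qrD)) * sum(res^2) / (n - ncol(D))
    }
    se <- sqrt(diag(cov))
    b_hat[surv_local] <- cf[med_pos]
    se_b[surv_local] <- se[med_pos]
    p_b[surv_local] <- 2 * pnorm(-abs(cf[med_pos] / se[med_pos]))
    c_prime_hat <- unname(cf[2L])
  } else {
    c_prime_hat <- mcp$coefficients[1L]
  }

  apath <- lapply(kept, function(t) fit_alpha_path(M[, t], X, covariates))
  a_hat <- vapply(apath, `[[`, numeric(1), "a_hat")
  se_a <- vapply(apath, `[[`, numeric(1), "se_a")
  p_a <- vapply(apath, `[[`, numeric(1), "p_a")

  total <- fit_total_effect(X, Y, covariates, family)

  assemble_mediation_result(
    method = "hima", k = k, kept = kept, scr = scr,
    a_hat = a_hat, se_a = se_a, p_a = p_a,
    b_hat = b_hat, se_b = se_b, p_b = p_b,
    b_lasso = NULL, total = total, c_prime_hat = c_prime_hat,
    control = control, family = family,
    mediator_ids = colnames(M),
    extra = list(mcp_lambda = mcp$lambda, mcp_gamma = mcp$gamma,
                 survivors = survivors)
  )
}
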