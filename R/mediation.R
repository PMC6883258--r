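#' Total-effect regression of outcome on exposure
#'
#' Fits `Y ~ X + covariates` by least squares (continuous outcome) or
#' logistic regression (binary outcome) and returns the exposure coefficient:
#' the total effect `c`, which the per-mediator indirect products are
#' expressed against.
#'
#' @param X exposure vector.
#' @param Y outcome vector.
#' @param covariates optional numeric matrix.
#' @param family `"binary"` or `"continuous"`.
#' @return list with `c_hat`, `se`, `p`.
#' @export
fit_total_effect <- function(X, Y, covariates = NULL,
                             family = c("binary", "continuous")) {
  family <- match.arg(family)
  if (var(X) == 0) stop("exposure is constant; total effect inestimable",
                        call. = FALSE)
  D <- cbind(`(Intercept)` = 1, X = X, covariates)
  if (family == "continuous") {
    qrD <- qr(D)
    cf <- qr.coef(qrD, Y)
    res <- qr.resid(qrD, Y)
    s2 <- sum(res^2) / (length(Y) - ncol(D))
    se <- sqrt(s2 * chol2inv(qr.R(qrD))[2L, 2L])
  } else {
    fit <- suppressWarnings(glm.fit(D, Y, family = binomial()))
    if (!fit$converged) stop("total-effect logistic fit did not converge ",
                             "(possible separation)", call. = FALSE)
    cf <- fit$coefficients
    cov <- tryCatch(chol2inv(chol(crossprod(D * sqrt(fit$weights)))),
                    error = function(e) stop("total-effect fit degenerate ",
                                             "(possible separation)",
                                             call. = FALSE))
    se <- sqrt(cov[2L, 2L])
  }
  if (!is.finite(se) || se <= 0) {
    stop("total-effect standard error degenerate", call. = FALSE)
  }
  c_hat <- unname(cf[2L])
  list(c_hat = c_hat, se = se, p = 2 * pnorm(-abs(c_hat / se)))
}

#' Exposure-to-mediator path estimate
#'
#' Ordinary least squares of one mediator on the exposure (plus covariates),
#' with the two-sided normal p-value `2(1 - Phi(|a_hat| / se))`.
#'
#' @param M_t length-n mediator vector.
#' @param X exposure vector.
#' @param covariates optional numeric matrix.
#' @return list with `a_hat`, `se_a`, `p_a`.
#' @export
fit_alpha_path <- function(M_t, X, covariates = NULL) {
  if (var(X) == 0) stop("exposure is constant; a-path inestimable",
                        call. = FALSE)
  D <- cbind(`(Intercept)` = 1, X = X, covariates)
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) stop("degenerate a-path design", call. = FALSE)
  cf <- qr.coef(qrD, M_t)
  res <- qr.resid(qrD, M_t)
  df <- length(M_t) - ncol(D)
  s2 <- sum(res^2) / df
  se <- sqrt(s2 * chol2inv(qr.R(qrD))[2L, 2L])
  a_hat <- unname(cf[2L])
  if (se == 0) {
    # exact linear relation: zero residual variance
    return(list(a_hat = a_hat, se_a = 0, p_a = 0))
  }
  list(a_hat = a_hat, se_a = se, p_a = 2 * pnorm(-abs(a_hat / se)))
}

#' Joint-significance (intersection-union) p-value
#'
#' The joint test rejects only when both path tests reject, so its p-value is
#' the maximum of the two component p-values.
#'
#' @param p_a,p_b component p-values in `[0, 1]`.
#' @return `max(p_a, p_b)` (vectorized).
#' @export
joint_pvalue <- function(p_a, p_b) {
  stopifnot(all(p_a >= 0 & p_a <= 1, na.rm = TRUE),
            all(p_b >= 0 & p_b <= 1, na.rm = TRUE))
  pmax(p_a, p_b)
}

#' Indirect effect and share of the total effect
#'
#' `ab = a_hat * b_hat`; the percentage of the total effect mediated is
#' reported on the absolute scale, `|ab| / |c_hat| * 100`, so that paths of
#' opposing sign still yield meaningful shares. Undefined (NA) when
#' `c_hat = 0`.
#'
#' @param a_hat,b_hat,c_hat path and total-effect estimates (vectorized over
#'   the first two).
#' @return list with `ab` and `pct_total`.
#' @export
effect_decomposition <- function(a_hat, b_hat, c_hat) {
  ab <- a_hat * b_hat
  pct <- if (is.na(c_hat) || c_hat == 0) rep(NA_real_, length(ab))
         else abs(ab) / abs(c_hat) * 100
  list(ab = ab, pct_total = pct)
}

#' High-dimensional mediation analysis (HDMA)
#'
#' The full testing pipeline for high-dimensional, possibly correlated
#' mediators:
#' \enumerate{
#'   \item sure independence screening reduces the mediators to
#'     `d = ceiling(n / (divisor * log n))` ([marginal_screen()]);
#'   \item the joint outcome model over the retained mediators (exposure and
#'     covariates unpenalized) is fitted by lasso and bias-corrected by the
#'     de-sparsified estimator ([debias_linear()] / [debias_logistic()]),
#'     giving a p-value `p_b` per retained mediator;
#'   \item the exposure-to-mediator path is tested by OLS per mediator
#'     ([fit_alpha_path()]);
#'   \item mediation is declared by the intersection-union rule
#'     `max(p_a, p_b) < alpha`.
#' }
#' The indirect products `a_hat * b_hat` are expressed as percentages of the
#' total effect from [fit_total_effect()].
#'
#' @param X length-n exposure vector (binary or continuous).
#' @param M `n x k` mediator matrix (column names become mediator ids).
#' @param Y length-n outcome.
#' @param covariates optional numeric matrix, included in all three
#'   regressions.
#' @param family `"binary"` or `"continuous"` outcome.
#' @param control an [hdma_control()].
#' @return object of class `"mediation_result"`; see [mediation_table()].
#' @export
hdma_test <- function(X, M, Y, covariates = NULL,
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

  log_stage(control, "de-sparsified %s lasso on %d retained mediators",
            family, length(kept))
  q <- if (is.null(covariates)) 0L else ncol(as.matrix(covariates))
  design <- cbind(X = X, covariates, M[, kept, drop = FALSE])
  unpen <- seq_len(1L + q)
  med_cols <- seq.int(2L + q, length.out = length(kept))
  fit <- if (family == "binary") {
    debias_logistic(design, Y, unpenalized = unpen,
                    columns = c(seq_len(1L + q), med_cols), control = control)
  } else {
    debias_linear(design, Y, unpenalized = unpen,
                  columns = c(seq_len(1L + q), med_cols), control = control)
  }
  idx_med <- match(med_cols, fit$columns)
  b_hat <- fit$estimates[idx_med]
  se_b <- fit$se[idx_med]
  p_b <- fit$pvalues[idx_med]
  c_prime_hat <- fit$estimates[match(1L, fit$columns)]

  log_stage(control, "a-path OLS and joint test")
  apath <- lapply(kept, function(t) fit_alpha_path(M[, t], X, covariates))
  a_hat <- vapply(apath, `[[`, numeric(1), "a_hat")
  se_a <- vapply(apath, `[[`, numeric(1), "se_a")
  p_a <- vapply(apath, `[[`, numeric(1), "p_a")

  total <- fit_total_effect(X, Y, covariates, family)

  assemble_mediation_result(
    method = "hdma", k = k, kept = kept, scr = scr,
    a_hat = a_hat, se_a = se_a, p_a = p_a,
    b_hat = b_hat, se_b = se_b, p_b = p_b,
    b_lasso = fit$lasso_coefficients[med_cols],
    total = total, c_prime_hat = c_prime_hat,
    control = control, family = family,
    mediator_ids = colnames(M), extra = list(lambda = fit$lambda,
                                             sigma_eps = fit$sigma_eps)
  )
}

# Shared assembly of the per-mediator results table for both methods.
# `b_hat`/`p_b` are aligned with `kept`; entries may be NA for mediators a
# method screened in but did not test (e.g. MCP non-survivors).
assemble_mediation_result <- function(method, k, kept, scr,
                                      a_hat, se_a, p_a, b_hat, se_b, p_b,
                                      b_lasso, total, c_prime_hat,
                                      control, family, mediator_ids,
                                      extra = list()) {
  alpha <- control$alpha
  p_joint <- joint_pvalue(ifelse(is.na(p_a), 1, p_a),
                          ifelse(is.na(p_b), 1, p_b))
  p_joint[is.na(p_a) & is.na(p_b)] <- NA_real_
  p_joint_adj <- if (identical(control$p_adjust, "none")) p_joint
                 else stats::p.adjust(p_joint, method = control$p_adjust)
  sig <- !is.na(p_a) & !is.na(p_b) & p_a < alpha & p_b < alpha &
    p_joint_adj < alpha
  dec <- effect_decomposition(a_hat, b_hat, total$c_hat)

  tab <- data.frame(
    mediator = seq_len(k),
    mediator_id = mediator_ids,
    status = "not_retained",
    score = scr$scores,
    a_hat = NA_real_, se_a = NA_real_, p_a = NA_real_,
    b_lasso = NA_real_, b_hat = NA_real_, se_b = NA_real_, p_b = NA_real_,
    ab = NA_real_, pct_total_effect = NA_real_,
    p_joint = NA_real_, significant = FALSE,
    stringsAsFactors = FALSE
  )
  tab$status[kept] <- "tested"
  tab$a_hat[kept] <- a_hat; tab$se_a[kept] <- se_a; tab$p_a[kept] <- p_a
  tab$b_hat[kept] <- b_hat; tab$se_b[kept] <- se_b; tab$p_b[kept] <- p_b
  if (!is.null(b_lasso)) tab$b_lasso[kept] <- b_lasso
  tab$ab[kept] <- dec$ab
  tab$pct_total_effect[kept] <- dec$pct_total
  tab$p_joint[kept] <- p_joint
  tab$significant[kept] <- sig
  tab$status[kept][is.na(b_hat)] <- "not_selected"

  S <- kept[!is.na(p_b) & p_b < alpha]
  structure(
    c(list(method = method, mediators = tab,
           c_hat = total$c_hat, c_se = total$se, c_p = total$p,
           c_prime_hat = c_prime_hat,
           alpha = alpha, S = sort(S), d = scr$d, sis_basis = scr$basis,
           family = family, control = control),
      extra),
    class = "mediation_result"
  )
}

#' Per-mediator results table
#'
#' @param result a `"mediation_result"` from [hdma_test()] or [hima_test()].
#' @param tested_only drop mediators the screen discarded.
#' @return data.frame, one row per mediator.
#' @export
mediation_table <- function(result, tested_only = FALSE) {
  stopifnot(inherits(result, "mediation_result"))
  tab <- result$mediators
  if (tested_only) tab <- tab[tab$status != "not_retained", , drop = FALSE]
  tab
}

#' Per-mediator rejection indicators
#'
#' Length-k logical vector of joint-test rejections; mediators not retained
#' by the screen (or not selected by the comparator's penalty) count as
#' non-rejections.
#'
#' @param result a `"mediation_result"`.
#' @export
rejections <- function(result) {
  stopifnot(inherits(result, "mediation_result"))
  result$mediators$significant
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("%s mediation analysis (%s outcome)\n",
              toupper(x$method), x$family))
  cat(sprintf("  screened to d = %d (%s); |S| = %d with p_b < %.3g\n",
              x$d, x$sis_basis, length(x$S), x$alpha))
  cat(sprintf("  total effect c = %.4f (se %.4f, p = %.3g); direct c' = %.4f\n",
              x$c_hat, x$c_se, x$c_p, x$c_prime_hat))
  sig <- x$mediators[x$mediators$significant, , drop = FALSE]
  if (nrow(sig) == 0) {
    cat("  no significant mediators at alpha =", x$alpha, "\n")
  } else {
    cat(sprintf("  %d significant mediator(s):\n", nrow(sig)))
    print(sig[, c("mediator_id", "a_hat", "b_hat", "ab",
                  "pct_total_effect", "p_joint")],
          row.names = FALSE, digits = 4)
  }
  invisible(x)
}
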