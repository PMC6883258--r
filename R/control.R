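#' Tuning parameters for the mediation testing pipelines
#'
#' Collects every tunable knob of [hdma_test()], [hima_test()] and the
#' Monte-Carlo harness in one place.
#'
#' @param alpha significance level for both path tests and the joint test
#'   (default 0.05, no multiplicity correction).
#' @param p_adjust multiplicity adjustment applied to the joint p-values
#'   before flagging significance: `"none"` (default), or any method accepted
#'   by [stats::p.adjust()] (e.g. `"bonferroni"`, `"BH"`).
#' @param sis_divisor screening keeps `ceiling(n / (sis_divisor * log(n)))`
#'   mediators; 1 (default) or 2 are the conventional choices.
#' @param sis_basis which regression the marginal screen ranks on:
#'   `"outcome_model"` (single-mediator outcome regression, the default) or
#'   `"mediator_model"` (exposure-to-mediator regression). Outcome-model
#'   screening is essential under correlated mediators: it retains
#'   outcome-associated mediators even when their exposure path is null, so
#'   the joint outcome model is not missing signal whose omission would bias
#'   the coefficients of correlated neighbours. Its cost is a mild
#'   post-selection optimism in `p_b` for marginally-retained null mediators;
#'   see the methods vignette.
#' @param lambda penalty level for the coefficient lasso; `NULL` (default)
#'   selects it by `lasso_nfolds`-fold cross-validation.
#' @param lasso_nfolds folds for the coefficient-lasso cross-validation.
#' @param nodewise_lambda how the nodewise-lasso penalties are chosen:
#'   `"cv"` (default) cross-validates each column separately;
#'   `"shared"` cross-validates `nodewise_probes` evenly spaced columns and
#'   applies their geometric-mean penalty to every column (much faster, used
#'   by the replication harness); or a fixed numeric value.
#' @param nodewise_nfolds folds for nodewise cross-validation.
#' @param nodewise_nlambda path length for nodewise cross-validation.
#' @param nodewise_probes number of probe columns in `"shared"` mode.
#' @param glm_variance per-coefficient variance form for the logistic
#'   de-sparsified estimator: `"fisher"` (default; the weighted-design
#'   covariance of the reference nodewise algorithm) or `"sandwich"` (the
#'   empirical score-outer-product form). The two coincide asymptotically
#'   under correct specification; the Fisher form is better calibrated at
#'   the sample sizes studied here.
#' @param weight_floor lower clip for the logistic variance weights
#'   `mu(1-mu)` before forming the weighted design (guards against rows with
#'   fitted probabilities numerically 0 or 1).
#' @param mcp_gamma MCP concavity parameter (> 1, default 3).
#' @param mcp_nlambda length of the MCP penalty grid searched by BIC.
#' @param mcp_lambda_min_ratio smallest grid penalty as a fraction of the
#'   largest.
#' @param verbose emit one progress line per pipeline stage.
#' @return object of class `"hdma_control"`.
#' @export
hdma_control <- function(alpha = 0.05,
                         p_adjust = "none",
                         sis_divisor = 1,
                         sis_basis = NULL,
                         lambda = NULL,
                         lasso_nfolds = 10,
                         nodewise_lambda = "cv",
                         nodewise_nfolds = 10,
                         nodewise_nlambda = 100,
                         nodewise_probes = 5,
                         glm_variance = c("fisher", "sandwich"),
                         weight_floor = 1e-8,
                         mcp_gamma = 3,
                         mcp_nlambda = 50,
                         mcp_lambda_min_ratio = 0.05,
                         verbose = FALSE) {
  if (!is.null(sis_basis)) {
    sis_basis <- match.arg(sis_basis, c("outcome_model", "mediator_model"))
  }
  glm_variance <- match.arg(glm_variance)
  stopifnot(alpha > 0, alpha < 1, sis_divisor > 0, mcp_gamma > 1)
  if (is.character(nodewise_lambda)) {
    nodewise_lambda <- match.arg(nodewise_lambda, c("cv", "shared"))
  } else {
    stopifnot(is.numeric(nodewise_lambda), nodewise_lambda >= 0)
  }
  structure(
    list(alpha = alpha, p_adjust = p_adjust, sis_divisor = sis_divisor,
         sis_basis = sis_basis, lambda = lambda,
         lasso_nfolds = lasso_nfolds,
         nodewise_lambda = nodewise_lambda,
         nodewise_nfolds = nodewise_nfolds,
         nodewise_nlambda = nodewise_nlambda,
         nodewise_probes = nodewise_probes,
         glm_variance = glm_variance,
         weight_floor = weight_floor,
         mcp_gamma = mcp_gamma, mcp_nlambda = mcp_nlambda,
         mcp_lambda_min_ratio = mcp_lambda_min_ratio,
         verbose = verbose),
    class = "hdma_control"
  )
}

#' Harness control preset
#'
#' The settings the Monte-Carlo replication harness runs with: identical to
#' [hdma_control()] except that nodewise penalties use the `"shared"`
#' cross-validation mode with a 30-point path and 5 folds, which cuts the
#' per-replication cost by roughly an order of magnitude at d ~ 100 while
#' leaving the de-sparsified estimator essentially unchanged (all nodewise
#' columns share the AR(1) scale).
#'
#' @param ... overrides passed to [hdma_control()].
#' @export
harness_control <- function(...) {
  hdma_control(nodewise_lambda = "shared", nodewise_nfolds = 5,
               nodewise_nlambda = 30, ...)
}

# Resolve the screening-basis default (outcome_model for both families).
resolve_sis_basis <- function(control, family) {
  if (!is.null(control$sis_basis)) return(control$sis_basis)
  "outcome_model"
}

log_stage <- function(control, fmt, ...) {
  if (isTRUE(control$verbose)) {
    message(sprintf("[hdma %s] %s", format(Sys.time(), "%H:%M:%OS1"),
                    sprintf(fmt, ...)))
  }
  invisible(NULL)
}
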