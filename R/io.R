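#' Read a labeled numeric matrix from delimited text
#'
#' Expects a header row and a sample-ID first column. Cells must be numeric
#' and complete: missing or non-numeric values are an error naming the
#' offending cell (the analysis assumes missingness was resolved upstream),
#' as are duplicated sample IDs.
#'
#' @param path CSV/TSV file path (delimiter sniffed by data.table).
#' @param orientation `"samples_in_rows"` (default) or
#'   `"features_in_rows"` (the matrix is transposed after reading).
#' @return numeric matrix with sample IDs as rownames.
#' @export
read_matrix <- function(path, orientation = c("samples_in_rows",
                                              "features_in_rows")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE,
                          colClasses = list(character = 1))
  ids <- as.character(dt[[1L]])
  if (anyDuplicated(ids)) {
    stop("duplicate sample IDs in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  body <- dt[, -1L, drop = FALSE]
  for (cn in names(body)) {
    col <- body[[cn]]
    if (!is.numeric(col)) {
      suppressWarnings(num <- as.numeric(col))
      bad <- which(is.na(num) & !is.na(col))
      if (length(bad) == 0) bad <- which(is.na(num))
      stop("non-numeric value in ", path, " at row ", bad[1L],
           " (sample ", ids[bad[1L]], "), column '", cn, "'", call. = FALSE)
    }
    if (anyNA(col)) {
      bad <- which(is.na(col))[1L]
      stop("missing value in ", path, " at row ", bad,
           " (sample ", ids[bad], "), column '", cn, "'", call. = FALSE)
    }
  }
  m <- as.matrix(body)
  rownames(m) <- ids
  if (orientation == "features_in_rows") m <- t(m)
  m
}

#' Align exposure/mediator/outcome inputs by sample ID
#'
#' Intersects the rownames of the supplied matrices (single-column matrices
#' for exposure/outcome are accepted) and returns all objects restricted to
#' the shared samples, in a common order. The number of samples dropped from
#' each input is reported via a message.
#'
#' @param ... named numeric matrices with sample-ID rownames.
#' @return named list of matrices over the common samples.
#' @export
align_samples <- function(...) {
  objs <- list(...)
  stopifnot(length(objs) >= 2, !is.null(names(objs)))
  ids <- Reduce(intersect, lapply(objs, rownames))
  if (length(ids) == 0) stop("no samples shared across inputs", call. = FALSE)
  for (nm in names(objs)) {
    dropped <- nrow(objs[[nm]]) - length(ids)
    if (dropped > 0) message("align_samples: dropped ", dropped,
                             " sample(s) from '", nm, "'")
  }
  lapply(objs, function(m) m[ids, , drop = FALSE])
}

#' Write mediation results to disk
#'
#' Writes `<prefix>_mediators.tsv` (the per-mediator table) and
#' `<prefix>_report.json` (run metadata: method, total and direct effects,
#' screening dimension, alpha, penalty levels, package version). The pair
#' round-trips losslessly through [read_results()].
#'
#' @param result a `"mediation_result"`.
#' @param prefix output path prefix.
#' @return invisibly, the two file paths.
#' @export
write_results <- function(result, prefix) {
  stopifnot(inherits(result, "mediation_result"))
  tsv <- paste0(prefix, "_mediators.tsv")
  json <- paste0(prefix, "_report.json")
  data.table::fwrite(result$mediators, tsv, sep = "\t")
  report <- list(
    method = result$method,
    family = result$family,
    alpha = result$alpha,
    c_hat = result$c_hat, c_se = result$c_se, c_p = result$c_p,
    c_prime_hat = result$c_prime_hat,
    d = result$d, sis_basis = result$sis_basis,
    sis_divisor = result$control$sis_divisor,
    S = result$S,
    n_significant = sum(result$mediators$significant),
    lambda = result$lambda,
    sigma_eps = result$sigma_eps,
    mcp_lambda = result$mcp_lambda,
    package_version = as.character(packageVersion("hdma"))
  )
  jsonlite::write_json(report[!vapply(report, is.null, logical(1))],
                       json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(tsv = tsv, json = json))
}

#' Read back a written mediator table
#'
#' @param prefix the prefix passed to [write_results()].
#' @return list with `mediators` (data.frame) and `report` (list).
#' @export
read_results <- function(prefix) {
  tsv <- paste0(prefix, "_mediators.tsv")
  json <- paste0(prefix, "_report.json")
  list(mediators = data.table::fread(tsv, data.table = FALSE),
       report = jsonlite::read_json(json, simplifyVector = TRUE))
}

#' Methylation beta-value / M-value conversion
#'
#' The analysis scale for methylation mediators is the M-value
#' `log(beta / (1 - beta))`; `m_to_beta()` is its inverse. The conversion is
#' never applied implicitly.
#'
#' @param beta methylation proportions in (0, 1).
#' @param m M-values.
#' @export
beta_to_m <- function(beta) {
  if (any(beta <= 0 | beta >= 1)) {
    stop("beta values must lie strictly in (0, 1)", call. = FALSE)
  }
  log(beta / (1 - beta))
}

#' @rdname beta_to_m
#' @export
m_to_beta <- function(m) 1 / (1 + exp(-m))

#' Write a simulated dataset as delimited text
#'
#' Emits `<prefix>_X.csv`, `<prefix>_M.csv`, `<prefix>_Y.csv`,
#' `<prefix>_truth.csv` (per-mediator ground truth) and
#' `<prefix>_config.json` (generative parameter echo), each with a sample-ID
#' or mediator-ID first column.
#'
#' @param sim an `"hdma_sim"` from [simulate_mediation()].
#' @param prefix output path prefix.
#' @return invisibly, the file paths.
#' @export
write_simulation <- function(sim, prefix) {
  stopifnot(inherits(sim, "hdma_sim"))
  ids <- sprintf("S%04d", seq_along(sim$X))
  paths <- c(X = paste0(prefix, "_X.csv"), M = paste0(prefix, "_M.csv"),
             Y = paste0(prefix, "_Y.csv"),
             truth = paste0(prefix, "_truth.csv"),
             config = paste0(prefix, "_config.json"))
  data.table::fwrite(data.frame(sample_id = ids, X = sim$X), paths["X"])
  data.table::fwrite(data.frame(sample_id = ids, sim$M), paths["M"])
  data.table::fwrite(data.frame(sample_id = ids, Y = sim$Y), paths["Y"])
  data.table::fwrite(data.frame(mediator_id = colnames(sim$M),
                                truth = as.integer(sim$truth),
                                truth_class = as.character(sim$truth_class)),
                     paths["truth"])
  cfg <- sim$config
  jsonlite::write_json(unclass(cfg)[!vapply(unclass(cfg), is.null,
                                            logical(1))],
                       paths["config"], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}
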