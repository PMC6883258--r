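#' One simulation replication
#'
#' Generates a dataset under `config` (with the given seed) and runs the
#' requested method, returning the length-k rejection indicator. Mediators
#' the screen or the penalty discarded count as non-rejections.
#'
#' @param config a [simulation_config()].
#' @param method `"hdma"` or `"hima"`.
#' @param seed integer seed for this replication.
#' @param control an [hdma_control()]; defaults to [harness_control()].
#' @return logical length-k vector.
#' @export
run_replication <- function(config, method = c("hdma", "hima"), seed,
                            control = harness_control()) {
  method <- match.arg(method)
  cfg <- config
  cfg$seed <- as.integer(seed)
  dat <- simulate_mediation(cfg)
  res <- if (method == "hdma") {
    hdma_test(dat$X, dat$M, dat$Y, family = cfg$family, control = control)
  } else {
    hima_test(dat$X, dat$M, dat$Y, family = cfg$family, control = control)
  }
  rejections(res)
}

# Both methods on the same dataset (paired seeds sharpen comparisons).
replication_pair <- function(config, methods, seed, control) {
  cfg <- config
  cfg$seed <- as.integer(seed)
  dat <- simulate_mediation(cfg)
  out <- list()
  for (m in methods) {
    out[[m]] <- tryCatch({
      res <- if (m == "hdma") {
        hdma_test(dat$X, dat$M, dat$Y, family = cfg$family, control = control)
      } else {
        hima_test(dat$X, dat$M, dat$Y, family = cfg$family, control = control)
      }
      rejections(res)
    }, error = function(e) {
      structure(conditionMessage(e), class = "replication_failure")
    })
  }
  out
}

#' Monte-Carlo power and type-I-error study
#'
#' Replicates the simulation design over a grid of `(n, k, rho, c_prime)`
#' cells, running both testing methods on the same generated datasets
#' (paired seeds), and aggregates per-mediator rejection rates: power for
#' mediators 1-4, type-I error for mediators 5-8, and the averaged rate over
#' the remaining k-8 nulls (`m_other`). Per-replication seeds are
#' `seed_base + replicate index` within each cell, so results are invariant
#' to the worker count and execution order.
#'
#' @param grid data.frame with columns `n`, `k`, `rho`, and optionally
#'   `c_prime` (default 0).
#' @param reps replications per cell.
#' @param methods character subset of `c("hdma", "hima")`.
#' @param seed_base integer; cell c uses seeds
#'   `seed_base + (c-1)*10^5 + 1:reps`.
#' @param workers parallel workers (forked; 1 = serial).
#' @param control an [hdma_control()] applied to every run.
#' @param family outcome family for the generator.
#' @return object of class `"power_table"`: a data.frame with one row per
#'   (cell, method) holding rejection rates `m1`..`m8`, `m_other`, `reps`,
#'   `failures`, and Monte-Carlo standard errors `mc_se_m1`..`mc_se_m4`;
#'   attribute `"rejections"` keeps the raw per-replication indicator
#'   matrices.
#' @export
run_power_study <- function(grid, reps = 200,
                            methods = c("hdma", "hima"),
                            seed_base = 1L, workers = 1L,
                            control = harness_control(),
                            family = "binary") {
  stopifnot(is.data.frame(grid), all(c("n", "k", "rho") %in% names(grid)),
            reps >= 1)
  methods <- match.arg(methods, several.ok = TRUE)
  if (is.null(grid$c_prime)) grid$c_prime <- 0
  rows <- list()
  raw <- list()
  for (ci in seq_len(nrow(grid))) {
    cell <- grid[ci, ]
    cfg <- simulation_config(n = cell$n, k = cell$k, rho = cell$rho,
                             c_prime = cell$c_prime, family = family)
    seeds <- seed_base + (ci - 1L) * 100000L + seq_len(reps)
    runner <- function(s) replication_pair(cfg, methods, s, control)
    pairs <- if (workers > 1L) {
      parallel::mclapply(seeds, runner, mc.cores = workers,
                         mc.preschedule = TRUE)
    } else {
      lapply(seeds, runner)
    }
    for (m in methods) {
      rej <- lapply(pairs, `[[`, m)
      failed <- vapply(rej, inherits, logical(1), "replication_failure")
      if (any(failed)) {
        warning(sprintf("cell %d (%s): %d failed replication(s)",
                        ci, m, sum(failed)))
      }
      R <- do.call(rbind, rej[!failed])   # reps_ok x k logical
      rate <- colMeans(R)
      n_ok <- nrow(R)
      row <- data.frame(
        n = cell$n, k = cell$k, rho = cell$rho, c_prime = cell$c_prime,
        method = m, reps = n_ok, failures = sum(failed)
      )
      for (j in 1:8) row[[paste0("m", j)]] <- rate[j]
      row$m_other <- mean(rate[-(1:8)])
      for (j in 1:4) {
        row[[paste0("mc_se_m", j)]] <- sqrt(rate[j] * (1 - rate[j]) / n_ok)
      }
      rows[[length(rows) + 1L]] <- row
      raw[[paste(ci, m, sep = ":")]] <- R
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "rejections") <- raw
  attr(out, "seed_base") <- seed_base
  class(out) <- c("power_table", class(out))
  out
}

#' @export
print.power_table <- function(x, ...) {
  cat("Monte-Carlo rejection rates (power: m1-m4; type I error: m5-m8, m_other)\n")
  print.data.frame(
    x[, c("n", "k", "rho", "c_prime", "method", "reps",
          paste0("m", 1:8), "m_other")],
    row.names = FALSE, digits = 3)
  invisible(x)
}

#' Long-format view of a power table
#'
#' @param x a `"power_table"`.
#' @return data.frame with columns cell identifiers, `mediator`, `rate`.
#' @export
power_table_long <- function(x) {
  stopifnot(inherits(x, "power_table"))
  meds <- c(paste0("m", 1:8), "m_other")
  do.call(rbind, lapply(meds, function(mm) {
    data.frame(n = x$n, k = x$k, rho = x$rho, c_prime = x$c_prime,
               method = x$method, mediator = mm, rate = x[[mm]],
               reps = x$reps)
  }))
}
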