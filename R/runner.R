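# Reproducible execution of the factorial simulation design.  Every
# (scenario, repetition) pair owns a counter-based random substream derived
# from the root seed, so all methods see the identical amputed dataset, the
# output is invariant to the worker count, and any single repetition can be
# reproduced in isolation.

#' Build a factorial scenario grid
#'
#' Crosses the supplied parameter values into one `data.frame` row per
#' scenario.  The full published design crosses
#' `n_total = c(100, 500, 1000)`, `prevalence = c(0.1, 0.3, 0.5)`,
#' `auc_true = c(0.7, 0.85, 0.9)`, `correlation = c(0.2, 0.5, 0.9)`,
#' `mechanism = c("MCAR", "MAR", "MNAR")` and
#' `prop_missing = c(0.1, 0.3, 0.5)` into 729 scenarios.
#'
#' @param n_total,prevalence,auc_true,correlation,mechanism,prop_missing
#'   vectors of parameter values to cross.
#' @param mnar_type amputation type for score-based mechanisms.
#' @return `data.frame` with one row per scenario and a `scenario_id` column.
#' @export
scenario_grid <- function(n_total = c(100, 500, 1000),
                          prevalence = c(0.1, 0.3, 0.5),
                          auc_true = c(0.7, 0.85, 0.9),
                          correlation = c(0.2, 0.5, 0.9),
                          mechanism = c("MCAR", "MAR", "MNAR"),
                          prop_missing = c(0.1, 0.3, 0.5),
                          mnar_type = "RIGHT") {
  g <- expand.grid(n_total = n_total, prevalence = prevalence,
                   auc_true = auc_true, correlation = correlation,
                   mechanism = mechanism, prop_missing = prop_missing,
                   mnar_type = mnar_type,
                   stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  g$scenario_id <- seq_len(nrow(g))
  g[, c("scenario_id", setdiff(names(g), "scenario_id"))]
}

# run all methods on one (scenario, repetition); returns a data.frame block
run_one_rep <- function(scen, rep_i, methods, seed, method_options) {
  set.seed(substream_seed(seed, scen$scenario_id, rep_i))
  cfg <- scenario_config(scen$n_total, scen$prevalence, scen$auc_true,
                         scen$correlation, scen$mechanism, scen$prop_missing,
                         scen$mnar_type)
  dat <- ampute_index(simulate_cohort(cfg), cfg$mechanism, cfg$prop_missing,
                      cfg$mnar_type)
  out <- vector("list", length(methods))
  for (mi in seq_along(methods)) {
    meth <- methods[mi]
    # method-keyed substream: adding or removing methods never perturbs the
    # data stream or the other methods' draws
    set.seed(substream_seed(seed, scen$scenario_id, rep_i, method_key(meth)))
    t0 <- proc.time()[["elapsed"]]
    est <- tryCatch(
      do.call(estimate_auc,
              c(list(data = dat, method = meth),
                method_options[[meth]] %||% list())),
      error = function(e) failed_estimate(meth, paste("error:",
                                                      conditionMessage(e))))
    row <- as.data.frame(est)
    row$runtime <- proc.time()[["elapsed"]] - t0
    out[[mi]] <- row
  }
  block <- do.call(rbind, out)
  cbind(scen[rep(1L, nrow(block)), , drop = FALSE],
        rep = rep_i, block, row.names = NULL)
}

#' Run a scenario grid across methods
#'
#' Executes `n_reps` repetitions of every scenario in `grid` for all
#' requested methods and returns a long-format results table with one row
#' per (scenario, repetition, method).  Within a repetition every method
#' receives the identical amputed dataset; estimator-internal randomness
#' (imputation draws, bootstrap) runs on a method-keyed substream.  Results
#' are deterministic given `seed` regardless of `workers`.
#'
#' @param grid a `data.frame` from [scenario_grid()] (or with the same
#'   columns).
#' @param methods character vector of method identifiers
#'   (see [available_methods()]).
#' @param n_reps repetitions per scenario.
#' @param seed root seed.
#' @param workers number of parallel (forked) workers; 1 = sequential.
#' @param method_options named list of per-method option lists, e.g.
#'   `list(aipw = list(n_boot = 0))`.
#' @return long-format `data.frame` with scenario parameters, `rep`,
#'   `method`, `auc`, `se`, `ci_lower`, `ci_upper`, `failed`,
#'   `failure_reason`, `runtime`.
#' @export
run_grid <- function(grid, methods, n_reps, seed = 1L, workers = 1L,
                     method_options = list()) {
  stopifnot(is.data.frame(grid), nrow(grid) > 0, n_reps >= 1)
  if (is.null(grid$scenario_id)) grid$scenario_id <- seq_len(nrow(grid))
  if (is.null(grid$mnar_type)) grid$mnar_type <- "RIGHT"
  unknown <- setdiff(methods, available_methods())
  if (length(unknown)) {
    stop("unknown method id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  tasks <- expand.grid(s = seq_len(nrow(grid)), r = seq_len(n_reps))
  worker <- function(ti) {
    run_one_rep(grid[tasks$s[ti], , drop = FALSE], tasks$r[ti], methods,
                seed, method_options)
  }
  blocks <- if (workers > 1L) {
    parallel::mclapply(seq_len(nrow(tasks)), worker, mc.cores = workers,
                       mc.preschedule = TRUE)
  } else {
    lapply(seq_len(nrow(tasks)), worker)
  }
  res <- do.call(rbind, blocks)
  res <- res[order(res$scenario_id, res$rep, match(res$method, methods)), ]
  rownames(res) <- NULL
  res
}

#' Tabulate failed estimates by design margin
#'
#' Aggregates the failed-repetition counts of a [run_grid()] results table
#' over true AUC, correlation and mechanism, reporting per
#' (n_total, prevalence, prop_missing) x method the number and percentage
#' of repetitions in which no AUC could be estimated.
#'
#' @param results long-format results from [run_grid()].
#' @return `data.frame` with columns `n_total`, `prevalence`,
#'   `prop_missing`, `method`, `n_reps`, `n_failed`, `pct_failed`.
#' @export
failure_table <- function(results) {
  stopifnot(all(c("n_total", "prevalence", "prop_missing", "method",
                  "failed") %in% names(results)))
  agg <- stats::aggregate(
    cbind(n_failed = results$failed, n_reps = rep(1L, nrow(results))),
    by = list(n_total = results$n_total, prevalence = results$prevalence,
              prop_missing = results$prop_missing, method = results$method),
    FUN = sum)
  agg$pct_failed <- 100 * agg$n_failed / agg$n_reps
  agg[order(agg$n_total, agg$prevalence, agg$prop_missing, agg$method), ]
}

#' Summarize a results table per scenario x method
#'
#' Applies [summarize_scenario()] to every scenario x method block of a
#' [run_grid()] results table, attaching the scenario parameters and the
#' scenario-specific `AUC_min` used for the power calculation.
#'
#' @param results long-format results from [run_grid()].
#' @param alpha significance level used for `AUC_min` (default 0.05).
#' @param beta design type-II error (default 0.2).
#' @param two_sided passed to [auc_min()].
#' @return `data.frame` with one row per scenario x method.
#' @export
summarize_results <- function(results, alpha = 0.05, beta = 0.2,
                              two_sided = FALSE) {
  keys <- unique(results[, c("scenario_id", "method")])
  out <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    block <- results[results$scenario_id == keys$scenario_id[i] &
                       results$method == keys$method[i], ]
    scen <- block[1L, c("scenario_id", "n_total", "prevalence", "auc_true",
                        "correlation", "mechanism", "prop_missing")]
    n_d <- round(scen$n_total * scen$prevalence)
    am <- suppressWarnings(
      auc_min(scen$auc_true, n_d, (scen$n_total - n_d) / n_d,
              alpha = alpha, beta = beta, two_sided = two_sided))
    summ <- summarize_scenario(block, scen$auc_true, as.numeric(am))
    out[[i]] <- cbind(scen, method = keys$method[i], auc_min = as.numeric(am),
                      summ, row.names = NULL)
  }
  do.call(rbind, out)
}
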