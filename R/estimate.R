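# Common contract for all estimators: map an incomplete diagnostic dataset
# to an `auc_estimate`.  A method that cannot produce an estimate returns a
# failed estimate with a reason; estimators never raise on data-dependent
# degeneracies.

#' Construct an AUC estimate object
#'
#' @param method method identifier.
#' @param auc,se,ci_lower,ci_upper estimate components.
#' @param n_imputations number of imputations, if applicable.
#' @param roc optional `roc_curve`.
#' @param ci_warning optional note about an interval boundary that could not
#'   be located (empirical likelihood profiling).
#' @return object of class `auc_estimate`.
#' @keywords internal
new_estimate <- function(method, auc, se, ci_lower, ci_upper,
                         n_imputations = NA_integer_, roc = NULL,
                         ci_warning = NA_character_) {
  structure(
    list(method = method, auc = auc, se = se,
         ci_lower = ci_lower, ci_upper = ci_upper,
         n_imputations = n_imputations, failed = FALSE,
         failure_reason = NA_character_, roc = roc, ci_warning = ci_warning),
    class = "auc_estimate")
}

failed_estimate <- function(method, reason) {
  structure(
    list(method = method, auc = NA_real_, se = NA_real_,
         ci_lower = NA_real_, ci_upper = NA_real_,
         n_imputations = NA_integer_, failed = TRUE,
         failure_reason = reason, roc = NULL, ci_warning = NA_character_),
    class = "auc_estimate")
}

#' @export
print.auc_estimate <- function(x, ...) {
  if (x$failed) {
    cat(sprintf("[%s] failed: %s\n", x$method, x$failure_reason))
  } else {
    cat(sprintf("[%s] AUC %.4f (se %.4f), 95%% CI [%.4f, %.4f]%s\n",
                x$method, x$auc, x$se, x$ci_lower, x$ci_upper,
                if (!is.na(x$ci_warning)) paste0(" [", x$ci_warning, "]") else ""))
  }
  invisible(x)
}

#' @export
as.data.frame.auc_estimate <- function(x, ...) {
  data.frame(method = x$method, auc = x$auc, se = x$se,
             ci_lower = x$ci_lower, ci_upper = x$ci_upper,
             n_imputations = x$n_imputations, failed = x$failed,
             failure_reason = x$failure_reason,
             stringsAsFactors = FALSE)
}

#' Methods available to the simulation runner
#' @return character vector of method identifiers.
#' @export
available_methods <- function() {
  c("cca", "mi-pmm", "mi-norm", "mi-joint", "mi-knn", "mi-knn-boot",
    "aipw", "ker", "hdel")
}

#' Estimate the AUC of an incomplete dataset by a named method
#'
#' Thin dispatcher over the individual estimators, used by [run_grid()].
#' Method identifiers: `"cca"` (complete case analysis), `"mi-pmm"` /
#' `"mi-norm"` (chained-equation MI with predictive mean matching / Bayesian
#' normal regression), `"mi-joint"` (general location model), `"mi-knn"` /
#' `"mi-knn-boot"` (nearest-neighbour score-based MI, without / with a
#' bootstrap step), `"aipw"` (augmented inverse probability weighting),
#' `"ker"` (kernel-smoothed inverse probability weighting) and `"hdel"`
#' (hot-deck imputation with an empirical likelihood interval).
#'
#' @param data a `diagnostic_dataset`.
#' @param method one of [available_methods()].
#' @param alpha two-sided significance level.
#' @param ... further options passed to the individual estimator.
#' @return an `auc_estimate`.
#' @export
estimate_auc <- function(data, method, alpha = 0.05, ...) {
  method <- match.arg(method, available_methods())
  switch(method,
    "cca" = estimate_cca(data, alpha),
    "mi-pmm" = estimate_mi_fcs(data, alpha, variant = "pmm", ...),
    "mi-norm" = estimate_mi_fcs(data, alpha, variant = "norm", ...),
    "mi-joint" = estimate_mi_joint(data, alpha, ...),
    "mi-knn" = estimate_mi_knn(data, alpha, bootstrap = FALSE, ...),
    "mi-knn-boot" = estimate_mi_knn(data, alpha, bootstrap = TRUE, ...),
    "aipw" = estimate_aipw(data, alpha, ...),
    "ker" = estimate_ker(data, alpha, ...),
    "hdel" = estimate_hdel(data, alpha, ...)
  )
}

# split helper: observed index values and covariate matrices by group
split_groups <- function(data) {
  validate_dataset(data)
  obs <- data$observed == 1L
  list(
    pos_obs = data$index[data$disease == 1L & obs],
    neg_obs = data$index[data$disease == 0L & obs],
    obs = obs,
    n_d = sum(data$disease == 1L),
    n_n = sum(data$disease == 0L)
  )
}

# covariate design matrix with intercept
cov_matrix <- function(data) {
  cbind(1, data$cov_bin, data$cov_c1, data$cov_c2)
}

# Rubin-pool trapezoidal AUCs with DeLong variances over completed index
# vectors; shared by all multiple-imputation estimators.
pool_imputed_auc <- function(method, data, completed_list, alpha) {
  m <- length(completed_list)
  aucs <- numeric(m); vars <- numeric(m)
  for (i in seq_len(m)) {
    idx <- completed_list[[i]]
    pos <- idx[data$disease == 1L]
    neg <- idx[data$disease == 0L]
    if (length(pos) < 2L || length(neg) < 2L) {
      return(failed_estimate(method, "fewer than 2 subjects in a disease group"))
    }
    dl <- delong_ci(pos, neg, alpha)
    aucs[i] <- dl$auc
    vars[i] <- dl$se^2
  }
  pl <- rubin_pool(aucs, vars, alpha)
  new_estimate(method, pl$pooled, pl$se, pl$ci_lower, pl$ci_upper,
               n_imputations = m)
}
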