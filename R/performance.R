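# Scenario-level performance measures: bias, RMSE, coverage, power against
# a minimally acceptable AUC derived from Obuchowski's sample-size formula,
# and Monte Carlo standard errors.

#' Obuchowski variance function for an AUC
#'
#' `V(theta) = (0.0099 * exp(-A^2/2)) * ((5 A^2 + 8) + (A^2 + 8)/k)` with
#' `A = qnorm(theta) * 1.414`, where `k` is the ratio of non-diseased to
#' diseased subjects.  `V(theta)/n_D` approximates the sampling variance of
#' the empirical AUC.  At `theta = 0.5` this reduces to `0.0792 (1 + 1/k)`,
#' the null-variance term of the sample-size formula.
#'
#' @param theta AUC in `(0.5, 1)` (`0.5` itself is allowed for the null term).
#' @param k ratio of non-diseased to diseased subjects (> 0).
#' @return the variance function value.
#' @export
#' @examples
#' variance_obuchowski(0.5, 1)  # 0.1584
variance_obuchowski <- function(theta, k) {
  if (theta < 0.5 || theta >= 1 || k <= 0) {
    stop("'theta' must lie in [0.5, 1) and 'k' must be positive", call. = FALSE)
  }
  a <- stats::qnorm(theta) * 1.414
  (0.0099 * exp(-a^2 / 2)) * ((5 * a^2 + 8) + (a^2 + 8) / k)
}

#' Minimally acceptable AUC from the inverted Obuchowski formula
#'
#' Inverts Obuchowski's sample-size formula
#' `n_D = (z_a * sqrt(0.0792 (1 + 1/k)) + z_b * sqrt(V(theta)))^2 /
#' (theta - AUC_min)^2` for the null AUC that the design of a study with
#' `n_diseased` diseased subjects can reject with power `1 - beta`:
#' `AUC_min = theta - (z_a * sqrt(0.0792 (1 + 1/k)) + z_b * sqrt(V(theta)))
#' / sqrt(n_D)`.
#'
#' By default `z_a` is the upper `alpha` quantile (one-sided, as in the
#' sample-size formula).  With `two_sided = TRUE` the upper `alpha/2`
#' quantile is used instead, consistent with a rejection rule that compares
#' the lower bound of the two-sided `1 - alpha` confidence interval against
#' `AUC_min` (see [summarize_scenario()]).
#'
#' @param theta true AUC in `(0.5, 1)`.
#' @param n_diseased number of diseased subjects (>= 2).
#' @param k ratio of non-diseased to diseased subjects.
#' @param alpha significance level (default 0.05).
#' @param beta type-II error (default 0.2, i.e. design power 80%).
#' @param two_sided use the upper `alpha/2` quantile for `z_a`.
#' @return the minimally acceptable AUC; values at or below 0.5 carry a
#'   `"degenerate"` attribute and a warning.
#' @export
#' @examples
#' auc_min(0.9, 50, 1)  # about 0.776
auc_min <- function(theta, n_diseased, k, alpha = 0.05, beta = 0.2,
                    two_sided = FALSE) {
  stopifnot(n_diseased >= 2)
  if (theta <= 0.5 || theta >= 1) stop("'theta' must lie in (0.5, 1)",
                                       call. = FALSE)
  z_a <- stats::qnorm(1 - if (two_sided) alpha / 2 else alpha)
  z_b <- stats::qnorm(1 - beta)
  out <- theta - (z_a * sqrt(0.0792 * (1 + 1 / k)) +
                    z_b * sqrt(variance_obuchowski(theta, k))) / sqrt(n_diseased)
  if (out <= 0.5) {
    warning("AUC_min at or below 0.5: degenerate design for this scenario")
    attr(out, "degenerate") <- TRUE
  }
  out
}

#' Summarize one scenario x method over simulation repetitions
#'
#' Computes, over the successful repetitions: bias (mean estimate minus
#' `auc_true`), RMSE, coverage (percentage of two-sided intervals containing
#' `auc_true`), power (percentage of repetitions whose lower confidence
#' bound exceeds `auc_min`, the rejection rule for H0: AUC <= AUC_min), and
#' the Monte Carlo standard errors of all four (RMSE by jackknife).  Failed
#' repetitions are excluded from the denominators and reported via
#' `n_failed`.
#'
#' @param estimates a `data.frame` with columns `auc`, `ci_lower`,
#'   `ci_upper`, `failed` (one row per repetition), or a list of
#'   `auc_estimate` objects.
#' @param auc_true true AUC of the scenario.
#' @param auc_min minimally acceptable AUC of the scenario (see [auc_min()]).
#' @return one-row `data.frame` with the performance measures and their
#'   Monte Carlo standard errors.
#' @export
summarize_scenario <- function(estimates, auc_true, auc_min) {
  if (is.list(estimates) && !is.data.frame(estimates)) {
    estimates <- do.call(rbind, lapply(estimates, as.data.frame))
  }
  stopifnot(all(c("auc", "ci_lower", "ci_upper", "failed") %in% names(estimates)))
  n_total <- nrow(estimates)
  ok <- !estimates$failed
  n_fail <- sum(!ok)
  if (!any(ok)) {
    return(data.frame(n_reps_total = n_total, n_failed = n_fail,
                      bias = NA_real_, rmse = NA_real_, coverage = NA_real_,
                      power = NA_real_, mce_bias = NA_real_, mce_rmse = NA_real_,
                      mce_coverage = NA_real_, mce_power = NA_real_))
  }
  a <- estimates$auc[ok]
  lo <- estimates$ci_lower[ok]
  hi <- estimates$ci_upper[ok]
  r <- length(a)
  bias <- mean(a) - auc_true
  sqerr <- (a - auc_true)^2
  rmse <- sqrt(mean(sqerr))
  cover <- mean(lo <= auc_true & auc_true <= hi)
  pow <- mean(lo > auc_min)
  # jackknife MCE for the RMSE
  mce_rmse <- if (r > 1L) {
    loo <- sqrt((sum(sqerr) - sqerr) / (r - 1L))
    sqrt((r - 1L) / r * sum((loo - mean(loo))^2))
  } else NA_real_
  data.frame(
    n_reps_total = n_total, n_failed = n_fail,
    bias = bias, rmse = rmse, coverage = 100 * cover, power = 100 * pow,
    mce_bias = stats::sd(a) / sqrt(r),
    mce_rmse = mce_rmse,
    mce_coverage = 100 * sqrt(cover * (1 - cover) / r),
    mce_power = 100 * sqrt(pow * (1 - pow) / r)
  )
}
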