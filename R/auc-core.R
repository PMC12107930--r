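# Core nonparametric AUC machinery: placement values, the trapezoidal /
# Wilcoxon-Mann-Whitney estimator, DeLong and Hanley-McNeil variances,
# empirical ROC curves, and Rubin's rules for pooling multiply imputed
# estimates.  Convention throughout: higher index values indicate disease,
# ties contribute 1/2.

#' Placement values of one sample within another
#'
#' `placement_values(x, ref)[i]` is the proportion of `ref` strictly below
#' `x[i]`, counting ties as 1/2.  The mean placement of the diseased sample
#' within the non-diseased sample is the Wilcoxon-Mann-Whitney AUC.
#'
#' @param x numeric vector of evaluation points.
#' @param ref nonempty numeric reference sample.
#' @return numeric vector in `[0, 1]`, same length as `x`.
#' @export
placement_values <- function(x, ref) {
  if (!length(ref)) stop("empty reference sample", call. = FALSE)
  sref <- sort(ref)
  n_le <- findInterval(x, sref)
  n_lt <- findInterval(x, sref, left.open = TRUE)
  (n_lt + 0.5 * (n_le - n_lt)) / length(ref)
}

#' Trapezoidal (Wilcoxon-Mann-Whitney) AUC
#'
#' The empirical probability that a randomly chosen diseased subject's index
#' value exceeds a randomly chosen non-diseased subject's, ties counted 1/2:
#' the area under the empirical ROC curve by the trapezoidal rule.
#'
#' @param pos index values of diseased subjects (nonempty).
#' @param neg index values of non-diseased subjects (nonempty).
#' @return the AUC, a number in `[0, 1]`.
#' @export
#' @examples
#' auc_trapezoid(c(3, 1), c(2, 0))  # 0.75
auc_trapezoid <- function(pos, neg) {
  pos <- pos[!is.na(pos)]; neg <- neg[!is.na(neg)]
  if (!length(pos) || !length(neg)) {
    stop("both samples must be nonempty", call. = FALSE)
  }
  mean(placement_values(pos, neg))
}

#' AUC with DeLong standard error and confidence interval
#'
#' Nonparametric variance of the WMW AUC from the two sets of placement
#' values: `se^2 = var(V10)/n_D + var(V01)/n_N`, where `V10` are the
#' placements of the diseased values within the non-diseased sample and
#' `V01` the complementary placements.  The Wald interval
#' `auc +/- z * se` is reported untransformed and untruncated.
#'
#' @param pos diseased index values (at least 2).
#' @param neg non-diseased index values (at least 2).
#' @param alpha two-sided significance level (default 0.05).
#' @return list with `auc`, `se`, `ci_lower`, `ci_upper`.
#' @export
delong_ci <- function(pos, neg, alpha = 0.05) {
  pos <- pos[!is.na(pos)]; neg <- neg[!is.na(neg)]
  if (length(pos) < 2L || length(neg) < 2L) {
    stop("DeLong variance needs at least 2 subjects per group", call. = FALSE)
  }
  v10 <- placement_values(pos, neg)
  v01 <- 1 - placement_values(neg, pos)
  auc <- mean(v10)
  se <- sqrt(stats::var(v10) / length(pos) + stats::var(v01) / length(neg))
  z <- stats::qnorm(1 - alpha / 2)
  list(auc = auc, se = se, ci_lower = auc - z * se, ci_upper = auc + z * se)
}

#' Hanley-McNeil standard error of an AUC
#'
#' Closed-form approximation based on the exponential model:
#' `se^2 = (Q0 + (nD - 1)(Q1 - theta^2) + (nN - 1)(Q2 - theta^2)) / (nD nN)`
#' with `Q0 = theta(1 - theta)`, `Q1 = theta / (2 - theta)` and
#' `Q2 = 2 theta^2 / (1 + theta)`.
#'
#' @param auc the AUC estimate in `(0, 1)`; values of exactly 0 or 1 return
#'   0 with a warning.
#' @param n_d number of diseased subjects.
#' @param n_n number of non-diseased subjects.
#' @return the standard error.
#' @export
hanley_mcneil_se <- function(auc, n_d, n_n) {
  stopifnot(n_d >= 1, n_n >= 1)
  if (auc < 0 || auc > 1) stop("'auc' must lie in [0, 1]", call. = FALSE)
  if (auc == 0 || auc == 1) {
    warning("degenerate AUC of 0 or 1; returning se = 0")
    return(0)
  }
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  v <- (auc * (1 - auc) + (n_d - 1) * (q1 - auc^2) + (n_n - 1) * (q2 - auc^2)) /
    (n_d * n_n)
  sqrt(max(v, 0))
}

#' Empirical (optionally weighted) ROC curve
#'
#' Step curve over all observed thresholds using weighted exceedance
#' proportions: for each threshold `c`, `fpr = P_w(neg > c)` and
#' `tpr = P_w(pos > c)`.  With unit weights its trapezoidal area equals
#' [auc_trapezoid()].  The curve starts at (0,0) and ends at (1,1); the
#' curve is invariant to rescaling all weights.
#'
#' @param pos,neg index values per group.
#' @param pos_weights,neg_weights nonnegative weights (default unit).
#' @return object of class `roc_curve`: list with nondecreasing `fpr`, `tpr`.
#' @export
empirical_roc <- function(pos, neg, pos_weights = NULL, neg_weights = NULL) {
  pos <- as.numeric(pos); neg <- as.numeric(neg)
  if (!length(pos) || !length(neg)) stop("both samples must be nonempty",
                                         call. = FALSE)
  pw <- pos_weights %||% rep(1, length(pos))
  nw <- neg_weights %||% rep(1, length(neg))
  if (any(pw < 0) || any(nw < 0)) stop("weights must be nonnegative",
                                       call. = FALSE)
  if (sum(pw) == 0 || sum(nw) == 0) {
    stop("weights must not be all zero within a group", call. = FALSE)
  }
  thr <- sort(unique(c(pos, neg)), decreasing = TRUE)
  # P_w(value > c) for c running down the thresholds, plus the (1,1) endpoint
  exceed <- function(v, w, cuts) {
    o <- order(v)
    v <- v[o]; w <- w[o] / sum(w)
    cum <- c(0, cumsum(w))
    # weight of values strictly greater than cut
    1 - cum[findInterval(cuts, v) + 1L]
  }
  fpr <- c(0, exceed(neg, nw, thr), 1)
  tpr <- c(0, exceed(pos, pw, thr), 1)
  structure(list(fpr = fpr, tpr = tpr), class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("empirical ROC curve with %d points, trapezoidal area %.4f\n",
              length(x$fpr), roc_area(x)))
  invisible(x)
}

#' Trapezoidal area under a `roc_curve`
#' @param roc a `roc_curve` object.
#' @return the area.
#' @export
roc_area <- function(roc) {
  sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
}

# sensitivity of a step ROC at given FPR values: sup{tpr : fpr <= t}
roc_sens_at <- function(roc, t) {
  tpr_max <- cummax(roc$tpr)
  idx <- findInterval(t, roc$fpr)
  out <- numeric(length(t))
  out[idx > 0] <- tpr_max[idx[idx > 0]]
  out
}

#' Pool estimates across imputations by Rubin's rules
#'
#' Pools `m` point estimates and within-imputation variances: the pooled
#' estimate is the mean, total variance `T = W + (1 + 1/m) B` with `W` the
#' mean within-imputation variance and `B` the between-imputation variance,
#' and the interval uses the Student-t reference with the classical Rubin
#' degrees of freedom `nu = (m - 1)(1 + W / ((1 + 1/m) B))^2`.  With a
#' single imputation or `B = 0` the normal reference is used.
#'
#' @param estimates numeric vector of per-imputation estimates.
#' @param variances matching vector of within-imputation variances.
#' @param alpha two-sided significance level.
#' @return list with `pooled`, `se`, `ci_lower`, `ci_upper`, `df`.
#' @export
#' @examples
#' rubin_pool(c(0.7, 0.9), c(0.01, 0.01))  # pooled 0.8, T = 0.04
rubin_pool <- function(estimates, variances, alpha = 0.05) {
  m <- length(estimates)
  if (m == 0L || length(variances) != m) {
    stop("'estimates' and 'variances' must be nonempty and equal length",
         call. = FALSE)
  }
  pooled <- mean(estimates)
  w <- mean(variances)
  b <- if (m > 1L) stats::var(estimates) else 0
  total <- w + (1 + 1 / m) * b
  if (m == 1L || b == 0) {
    df <- Inf
    q <- stats::qnorm(1 - alpha / 2)
  } else {
    df <- (m - 1) * (1 + w / ((1 + 1 / m) * b))^2
    q <- stats::qt(1 - alpha / 2, df)
  }
  se <- sqrt(total)
  list(pooled = pooled, se = se,
       ci_lower = pooled - q * se, ci_upper = pooled + q * se, df = df)
}
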