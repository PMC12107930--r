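# Owen-style empirical likelihood for a univariate mean, used to profile a
# confidence interval for the AUC through the diseased placement values.

# -2 log empirical likelihood ratio for mean(v) = mu.
# Infinite outside the open range (min(v), max(v)).
el_loglik_ratio <- function(v, mu) {
  n <- length(v)
  d <- v - mu
  if (mu <= min(v) || mu >= max(v)) return(Inf)
  if (all(abs(d) < 1e-14)) return(0)
  # solve sum(d / (1 + lambda d)) = 0 on the interval where all
  # 1 + lambda d > 0; the estimating function is strictly decreasing.
  lo <- -1 / max(d) * (1 - 1e-10)
  hi <- -1 / min(d) * (1 - 1e-10)
  gfun <- function(l) sum(d / (1 + l * d))
  glo <- gfun(lo); ghi <- gfun(hi)
  if (!is.finite(glo) || !is.finite(ghi) || glo * ghi > 0) return(Inf)
  lam <- stats::uniroot(gfun, c(lo, hi), tol = 1e-12)$root
  2 * sum(log1p(lam * d))
}

# Two-sided EL confidence interval for the mean of v, chi-squared(1)
# calibrated; each bound located by bisection between the point estimate
# and the attainable range limit.  Bounds that cannot be bracketed are
# clamped to the attainable limit with a warning note.
el_mean_ci <- function(v, alpha = 0.05, tol = 1e-6) {
  mu_hat <- mean(v)
  lim <- range(v)
  if (lim[1] == lim[2]) {
    return(list(lower = mu_hat, upper = mu_hat,
                warning = "degenerate placement distribution; no EL interval"))
  }
  crit <- stats::qchisq(1 - alpha, df = 1)
  f <- function(mu) el_loglik_ratio(v, mu) - crit
  warn <- NULL
  eps <- 1e-9 * diff(lim)
  bound <- function(side) {
    a <- if (side == "lower") lim[1] + eps else mu_hat
    b <- if (side == "lower") mu_hat else lim[2] - eps
    if (b <= a) {
      warn <<- c(warn, paste0(side, " EL bound outside attainable range"))
      return(if (side == "lower") lim[1] else lim[2])
    }
    edge <- if (side == "lower") a else b
    fe <- f(edge)
    for (i in 1:20) {  # step inward off a numerically infinite edge
      if (is.finite(fe)) break
      edge <- edge + (if (side == "lower") 1 else -1) * 2^i * eps
      fe <- f(edge)
    }
    if (!is.finite(fe) || fe < 0) {
      warn <<- c(warn, paste0(side, " EL bound outside attainable range"))
      return(if (side == "lower") lim[1] else lim[2])
    }
    if (side == "lower") stats::uniroot(f, c(edge, b), tol = tol)$root
    else stats::uniroot(f, c(a, edge), tol = tol)$root
  }
  lower <- bound("lower")
  upper <- bound("upper")
  list(lower = lower, upper = upper,
       warning = if (is.null(warn)) NA_character_ else paste(warn, collapse = "; "))
}
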