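# The compared estimators (general location model MI lives in joint-mi.R).

#' Complete case analysis
#'
#' Drops all subjects with a missing index value and reports the trapezoidal
#' AUC with a DeLong interval.  Fails when either disease group retains
#' fewer than two complete cases.
#'
#' @param data a `diagnostic_dataset`.
#' @param alpha two-sided significance level.
#' @return an `auc_estimate`.
#' @export
estimate_cca <- function(data, alpha = 0.05) {
  g <- split_groups(data)
  if (length(g$pos_obs) < 2L || length(g$neg_obs) < 2L) {
    return(failed_estimate("cca", "fewer than 2 complete cases in a disease group"))
  }
  dl <- delong_ci(g$pos_obs, g$neg_obs, alpha)
  est <- new_estimate("cca", dl$auc, dl$se, dl$ci_lower, dl$ci_upper)
  est$roc <- empirical_roc(g$pos_obs, g$neg_obs)
  est
}

# One Bayesian draw of the normal linear regression of the index on
# covariates + disease fitted to complete cases (noninformative prior).
# Aliased columns (for example the disease indicator when one group has no
# complete cases left) are dropped from the model, coefficient 0.  Returns
# NULL only when no residual degrees of freedom remain.
bayes_lm_draw <- function(X_obs, y_obs) {
  n <- nrow(X_obs); p <- ncol(X_obs)
  qr0 <- qr(X_obs)
  r <- qr0$rank
  if (n <= r) return(NULL)
  keep <- sort(qr0$pivot[seq_len(r)])
  qrX <- qr(X_obs[, keep, drop = FALSE])
  bh <- qr.coef(qrX, y_obs)
  rss <- sum(qr.resid(qrX, y_obs)^2)
  sigma2 <- rss / stats::rchisq(1, df = n - r)
  R <- qr.R(qrX)
  bs <- bh + sqrt(sigma2) * backsolve(R, stats::rnorm(r))
  beta_hat <- beta_star <- numeric(p)
  beta_hat[keep] <- bh
  beta_star[keep] <- bs
  list(beta_hat = beta_hat, beta_star = beta_star, sigma = sqrt(sigma2))
}

#' Chained-equation multiple imputation (single incomplete variable)
#'
#' Fully conditional specification with the index test as the only
#' incomplete variable, so the chained system reduces to one Bayesian
#' normal linear regression of the index on the three covariates and the
#' reference standard, fitted to the complete cases.  Each of the `m`
#' imputations draws regression parameters from their posterior under a
#' noninformative prior; variant `"norm"` then imputes from the predictive
#' normal, variant `"pmm"` (predictive mean matching) imputes the observed
#' index value of a donor drawn uniformly from the `donors` complete cases
#' whose predicted means (under the posterior-mean fit) lie closest to the
#' target's predicted mean (under the drawn parameters).  Completed
#' datasets are analysed by the trapezoidal AUC with DeLong variance and
#' pooled by Rubin's rules.
#'
#' @param data a `diagnostic_dataset`.
#' @param alpha two-sided significance level.
#' @param variant `"pmm"` or `"norm"`.
#' @param m number of imputations (default 20).
#' @param donors size of the PMM donor pool (default 5).
#' @return an `auc_estimate`.
#' @export
estimate_mi_fcs <- function(data, alpha = 0.05, variant = c("pmm", "norm"),
                            m = 20L, donors = 5L) {
  variant <- match.arg(variant)
  method <- paste0("mi-", variant)
  g <- split_groups(data)
  if (all(g$obs)) {  # imputation is a no-op on complete data
    if (length(g$pos_obs) < 2L || length(g$neg_obs) < 2L) {
      return(failed_estimate(method, "fewer than 2 subjects in a disease group"))
    }
    dl <- delong_ci(g$pos_obs, g$neg_obs, alpha)
    return(new_estimate(method, dl$auc, dl$se, dl$ci_lower, dl$ci_upper,
                        n_imputations = m))
  }
  X <- cbind(cov_matrix(data), data$disease)
  X_obs <- X[g$obs, , drop = FALSE]
  X_mis <- X[!g$obs, , drop = FALSE]
  y_obs <- data$index[g$obs]
  completed <- vector("list", m)
  for (i in seq_len(m)) {
    dr <- bayes_lm_draw(X_obs, y_obs)
    if (is.null(dr)) {
      return(failed_estimate(method,
                             "too few complete cases for the imputation model"))
    }
    yhat_mis <- drop(X_mis %*% dr$beta_star)
    imp <- if (variant == "norm") {
      yhat_mis + dr$sigma * stats::rnorm(nrow(X_mis))
    } else {
      pmm_match(drop(X_obs %*% dr$beta_hat), y_obs, yhat_mis, donors)
    }
    idx <- data$index
    idx[!g$obs] <- imp
    completed[[i]] <- idx
  }
  pool_imputed_auc(method, data, completed, alpha)
}

# Predictive-mean-matching donor draw: for each target predicted mean,
# draw one observed value from the `donors` nearest observed predicted
# means.  The nearest donors lie in a fixed-width window around the
# insertion point of the sorted observed means, so no per-target sort is
# needed.
pmm_match <- function(yhat_obs, y_obs, yhat_mis, donors) {
  n_obs <- length(y_obs)
  n_mis <- length(yhat_mis)
  k <- min(donors, n_obs)
  o <- order(yhat_obs)
  s <- yhat_obs[o]
  ys <- y_obs[o]
  pos <- findInterval(yhat_mis, s)
  # contiguous candidate window of width 2k around each insertion point:
  # the k nearest sorted neighbours always lie inside it
  width <- min(2L * k, n_obs)
  lo <- pmin(pmax(pos - k + 1L, 1L), n_obs - width + 1L)
  idx <- outer(lo, seq_len(width) - 1L, "+")
  dist <- abs(matrix(s[idx], n_mis) - yhat_mis)
  # pick the k nearest per row by repeated column-minimum extraction, then
  # draw one of them uniformly
  pick <- sample.int(k, n_mis, replace = TRUE)
  out <- numeric(n_mis)
  rows <- seq_len(n_mis)
  for (j in seq_len(k)) {
    nearest <- max.col(-dist, ties.method = "first")
    hit <- pick == j
    out[hit] <- ys[idx[cbind(rows[hit], nearest[hit])]]
    dist[cbind(rows, nearest)] <- Inf
  }
  out
}

# fit the two score models used by the kNN imputers:
# propensity = P(index observed | covariates), ridge-logistic on all rows;
# prediction = E(index | covariates), least squares on complete cases.
# Returns coefficient vectors so scores can be evaluated on any rows.
# Aliased prediction columns are dropped (coefficient 0); a (quasi-)
# separated propensity fit is still a usable matching score after
# standardization, so it is not treated as a failure here.
fit_score_models <- function(X, observed, index) {
  prop_fit <- ridge_logistic(X, as.numeric(observed))
  obs <- observed == 1L
  co <- qr.coef(qr(X[obs, , drop = FALSE]), index[obs])
  co[is.na(co)] <- 0
  list(prop_coef = prop_fit$coef, pred_coef = co)
}

#' Nearest-neighbour score-based multiple imputation (with optional bootstrap)
#'
#' Identifies, for every subject with a missing index value, the `k` nearest
#' complete cases within the same disease group in the two-dimensional space
#' of a standardized propensity score (probability that the index is
#' observed, logistic on the three covariates) and a standardized prediction
#' score (linear regression of the index on the three covariates, fitted to
#' complete cases).  Each of `m` imputations draws one donor uniformly from
#' the neighbours.  With `bootstrap = TRUE`, each imputation first resamples
#' the dataset with replacement and re-estimates both scores on the
#' resample before matching (donors remain the original complete cases).
#' Completed datasets are pooled by Rubin's rules.
#'
#' If a disease group has fewer than `k` complete cases the donor pool
#' shrinks to those available; the method fails only when a group has no
#' observed index values at all.
#'
#' @param data a `diagnostic_dataset`.
#' @param alpha two-sided significance level.
#' @param k number of nearest neighbours (default 3).
#' @param m number of imputations (default 10).
#' @param bootstrap re-estimate the scores on a with-replacement resample
#'   before each imputation.
#' @return an `auc_estimate`.
#' @export
estimate_mi_knn <- function(data, alpha = 0.05, k = 3L, m = 10L,
                            bootstrap = FALSE) {
  method <- if (bootstrap) "mi-knn-boot" else "mi-knn"
  g <- split_groups(data)
  if (all(g$obs)) {
    if (length(g$pos_obs) < 2L || length(g$neg_obs) < 2L) {
      return(failed_estimate(method, "fewer than 2 subjects in a disease group"))
    }
    dl <- delong_ci(g$pos_obs, g$neg_obs, alpha)
    return(new_estimate(method, dl$auc, dl$se, dl$ci_lower, dl$ci_upper,
                        n_imputations = m))
  }
  if (!length(g$pos_obs) || !length(g$neg_obs)) {
    return(failed_estimate(method, "no observed index values in a disease group"))
  }
  X <- cov_matrix(data)
  n <- nrow(data)
  base_fit <- fit_score_models(X, data$observed, data$index)
  if (is.null(base_fit)) {
    return(failed_estimate(method, "singular or separated score model"))
  }
  mis_idx <- which(g$obs == FALSE)
  pools <- lapply(c(0L, 1L), function(grp) which(data$disease == grp & g$obs))
  # k nearest in-group complete cases per missing subject, in the
  # standardized (propensity, prediction) score plane
  neighbours_for <- function(fit) {
    s1 <- standardize(stats::plogis(drop(X %*% fit$prop_coef)))
    s2 <- standardize(drop(X %*% fit$pred_coef))
    lapply(mis_idx, function(j) {
      pool_rows <- pools[[data$disease[j] + 1L]]
      d2 <- (s1[pool_rows] - s1[j])^2 + (s2[pool_rows] - s2[j])^2
      pool_rows[order(d2)[seq_len(min(k, length(pool_rows)))]]
    })
  }
  base_nb <- if (bootstrap) NULL else neighbours_for(base_fit)
  completed <- vector("list", m)
  for (i in seq_len(m)) {
    nb <- base_nb
    if (bootstrap) {
      repeat {
        bs <- sample.int(n, n, replace = TRUE)
        if (any(data$observed[bs] == 1L) && any(data$observed[bs] == 0L)) break
      }
      fit <- fit_score_models(X[bs, , drop = FALSE], data$observed[bs],
                              data$index[bs])
      # degenerate resample (all-NA refit): fall back to the original fit
      if (is.null(fit) || anyNA(fit$pred_coef)) fit <- base_fit
      nb <- neighbours_for(fit)
    }
    idx <- data$index
    idx[mis_idx] <- vapply(nb, function(v) {
      data$index[v[sample.int(length(v), 1L)]]
    }, numeric(1))
    completed[[i]] <- idx
  }
  pool_imputed_auc(method, data, completed, alpha)
}

# AIPW point estimate on one dataset; NULL when inestimable.
aipw_point <- function(disease, index, X, observed, min_group_complete,
                       prop_floor = 1e-3) {
  obs <- observed == 1L
  cd <- sum(disease == 1L & obs)
  cn <- sum(disease == 0L & obs)
  if (cd < min_group_complete || cn < min_group_complete) return(NULL)
  if (all(obs)) {
    e <- rep(1, length(disease))
  } else {
    pf <- ridge_logistic(X, as.numeric(observed))
    if (pf$separated) return(NULL)
    e <- pmax(pf$fitted, prop_floor)
  }
  # group-wise prediction models for the augmentation term; aliased
  # columns are dropped (coefficient 0), as a least-squares fit would
  fit_group <- function(rows) {
    Xr <- X[rows, , drop = FALSE]
    qrX <- qr(Xr)
    if (length(rows) <= qrX$rank) return(NULL)  # no residual df
    co <- qr.coef(qrX, index[rows])
    co[is.na(co)] <- 0
    s2 <- sum((index[rows] - drop(Xr %*% co))^2) / (length(rows) - qrX$rank)
    list(coef = co, s2 = s2)
  }
  fd <- fit_group(which(disease == 1L & obs))
  fn <- fit_group(which(disease == 0L & obs))
  if (is.null(fd) || is.null(fn)) return(NULL)
  id <- which(disease == 1L); jn <- which(disease == 0L)
  md <- drop(X[id, , drop = FALSE] %*% fd$coef)
  mn <- drop(X[jn, , drop = FALSE] %*% fn$coef)
  sdsum <- sqrt(fd$s2 + fn$s2)
  # model-based pairwise concordance P(Y_i > Y_j | covariates)
  phi <- stats::pnorm(outer(md, mn, "-") / max(sdsum, 1e-12))
  vi <- as.numeric(obs[id]); vj <- as.numeric(obs[jn])
  ee <- outer(e[id], e[jn])
  vv <- outer(vi, vj)
  yi <- index[id]; yi[is.na(yi)] <- 0  # masked by vv = 0
  yj <- index[jn]; yj[is.na(yj)] <- 0
  psi <- (outer(yi, yj, ">") + 0.5 * outer(yi, yj, "==")) * vv
  u <- (vv / ee) * psi - ((vv - ee) / ee) * phi
  min(max(mean(u), 0), 1)
}

#' Augmented inverse probability weighted AUC
#'
#' Doubly robust pairwise estimator: concordance indicators of fully
#' observed pairs are weighted by the inverse product of observedness
#' propensities (logistic regression on the three covariates), and a
#' model-based augmentation term -- the normal-model concordance probability
#' from group-wise linear regressions of the index on the covariates --
#' substitutes for pairs with unobserved members.  On complete data all
#' weights are 1 and the estimator reduces to the trapezoidal AUC.  The
#' interval is the percentile interval over `n_boot` nonparametric bootstrap
#' resamples stratified by disease group (`n_boot = 0` skips the interval).
#'
#' The estimate fails when either disease group has fewer than
#' `min_group_complete` complete cases (the group-wise prediction model
#' needs its four coefficients plus residual degrees of freedom) or when a
#' score model is singular or separated.  Inestimable bootstrap replicates
#' are dropped from the percentile interval.
#'
#' @param data a `diagnostic_dataset`.
#' @param alpha two-sided significance level.
#' @param n_boot bootstrap resamples for the CI (default 200).
#' @param min_group_complete minimum complete cases per disease group
#'   (default 6).
#' @return an `auc_estimate`.
#' @export
estimate_aipw <- function(data, alpha = 0.05, n_boot = 200L,
                          min_group_complete = 6L) {
  validate_dataset(data)
  X <- cov_matrix(data)
  pt <- aipw_point(data$disease, data$index, X, data$observed,
                   min_group_complete)
  if (is.null(pt)) {
    return(failed_estimate("aipw",
      "too few complete cases in a disease group for the prediction score"))
  }
  if (n_boot <= 0L) {
    return(new_estimate("aipw", pt, NA_real_, NA_real_, NA_real_))
  }
  id <- which(data$disease == 1L); jn <- which(data$disease == 0L)
  boots <- numeric(n_boot); ok <- logical(n_boot)
  for (b in seq_len(n_boot)) {
    rows <- c(sample(id, length(id), replace = TRUE),
              sample(jn, length(jn), replace = TRUE))
    bp <- aipw_point(data$disease[rows], data$index[rows],
                     X[rows, , drop = FALSE], data$observed[rows],
                     min_group_complete)
    if (!is.null(bp)) { boots[b] <- bp; ok[b] <- TRUE }
  }
  if (!any(ok)) {
    return(failed_estimate("aipw", "all bootstrap replicates inestimable"))
  }
  qs <- stats::quantile(boots[ok], c(alpha / 2, 1 - alpha / 2), names = FALSE)
  # percentile bounds are widened, if necessary, to contain the point estimate
  new_estimate("aipw", pt, stats::sd(boots[ok]),
               min(qs[1], pt), max(qs[2], pt))
}

#' Kernel-smoothed inverse probability weighted AUC
#'
#' Estimates the observedness propensity by Nadaraya-Watson kernel
#' regression on the three covariates (Gaussian product kernel, Silverman
#' bandwidth per coordinate), weights each complete case by the inverse
#' propensity (floored at `prop_floor`), forms the weighted empirical ROC,
#' and reports the mean sensitivity over an equally spaced midpoint grid of
#' `grid_size` false positive rates in (0, 1).  The standard error follows
#' Hanley-McNeil with complete-case group sizes.
#'
#' @param data a `diagnostic_dataset`.
#' @param alpha two-sided significance level.
#' @param grid_size number of FPR grid points (default 101).
#' @param prop_floor lower bound for estimated propensities (default 1e-3).
#' @return an `auc_estimate` with the weighted `roc_curve` attached.
#' @export
estimate_ker <- function(data, alpha = 0.05, grid_size = 101L,
                         prop_floor = 1e-3) {
  g <- split_groups(data)
  if (!length(g$pos_obs) || !length(g$neg_obs)) {
    return(failed_estimate("ker", "no complete cases in a disease group"))
  }
  obs <- g$obs
  if (all(obs)) {
    w <- rep(1, nrow(data))
  } else {
    Z <- cbind(data$cov_bin, data$cov_c1, data$cov_c2)
    n <- nrow(Z)
    bw <- apply(Z, 2, function(z) {
      s <- stats::sd(z)
      if (!is.finite(s) || s == 0) s <- 1e-6
      1.06 * s * n^(-1 / 5)
    })
    kmat <- matrix(1, sum(obs), n)
    zo <- Z[obs, , drop = FALSE]
    for (j in 1:3) {
      kmat <- kmat * stats::dnorm(outer(zo[, j], Z[, j], "-") / bw[j])
    }
    e <- drop(kmat %*% as.numeric(data$observed)) / rowSums(kmat)
    e_full <- numeric(n)
    e_full[obs] <- pmax(e, prop_floor)
    if (any(e <= prop_floor)) {
      warning("kernel propensity floored at ", prop_floor,
              " for some complete cases")
    }
    w <- 1 / e_full
  }
  pos_rows <- data$disease == 1L & obs
  neg_rows <- data$disease == 0L & obs
  roc <- empirical_roc(data$index[pos_rows], data$index[neg_rows],
                       w[pos_rows], w[neg_rows])
  grid <- (seq_len(grid_size) - 0.5) / grid_size
  auc <- mean(roc_sens_at(roc, grid))
  se <- hanley_mcneil_se(min(max(auc, 1e-12), 1 - 1e-12),
                         length(g$pos_obs), length(g$neg_obs))
  z <- stats::qnorm(1 - alpha / 2)
  new_estimate("ker", auc, se, auc - z * se, auc + z * se, roc = roc)
}

#' Hot-deck imputation with an empirical likelihood interval
#'
#' Imputes each missing index value by a uniform with-replacement draw from
#' the observed index values of the same disease group (valid under MCAR),
#' takes the Wilcoxon-Mann-Whitney AUC of the completed data as the point
#' estimate, and profiles an empirical likelihood ratio for the mean of the
#' diseased placement values, calibrated against the chi-squared(1)
#' quantile, to obtain the interval.  A bound that cannot be bracketed
#' inside the attainable placement range is replaced by the attainable
#' bound, and the estimate carries a `ci_warning`.
#'
#' @param data a `diagnostic_dataset`.
#' @param alpha two-sided significance level.
#' @return an `auc_estimate`.
#' @export
estimate_hdel <- function(data, alpha = 0.05) {
  g <- split_groups(data)
  if (!length(g$pos_obs) || !length(g$neg_obs)) {
    return(failed_estimate("hdel", "no observed index values in a disease group"))
  }
  idx <- data$index
  for (grp in c(0L, 1L)) {
    mis <- which(data$disease == grp & g$obs == FALSE)
    donors <- data$index[data$disease == grp & g$obs]
    if (length(mis)) idx[mis] <- donors[sample.int(length(donors),
                                                   length(mis), replace = TRUE)]
  }
  pos <- idx[data$disease == 1L]
  neg <- idx[data$disease == 0L]
  v <- placement_values(pos, neg)
  auc <- mean(v)
  ci <- el_mean_ci(v, alpha)
  se <- if (length(pos) >= 2L && length(neg) >= 2L) {
    delong_ci(pos, neg, alpha)$se
  } else NA_real_
  est <- new_estimate("hdel", auc, se, ci$lower, ci$upper,
                      ci_warning = ci$warning)
  est$roc <- empirical_roc(pos, neg)
  est
}
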