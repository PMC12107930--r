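# Joint-model multiple imputation under an unrestricted general location
# model: the categorical part is the cross-classification of the reference
# standard with the binary covariate, and conditionally on the cell the
# continuous block (index, cov_c1, cov_c2) is multivariate normal with
# cell-specific means and a common covariance matrix.  Only the index test
# can be missing.  Parameters are estimated by EM, then imputations are
# drawn by data augmentation from an approximate posterior under a
# noninformative prior.

# log density of multivariate normal rows (small fixed dimension)
dmvnorm_log <- function(Y, mu, sigma) {
  p <- ncol(Y)
  ch <- chol(sigma)
  z <- forwardsolve(t(ch), t(Y) - mu)
  -0.5 * colSums(z^2) - sum(log(diag(ch))) - 0.5 * p * log(2 * pi)
}

# EM for the general location model with missingness confined to the first
# continuous coordinate.  `cell` is an integer cell label per subject.
# Returns cell means, common covariance, and the observed-data
# log-likelihood trace (nondecreasing by construction).
glm_em <- function(Y, cell, max_iter = 200L, tol = 1e-8) {
  n <- nrow(Y)
  cells <- sort(unique(cell))
  mis <- is.na(Y[, 1])
  p_cell <- vapply(cells, function(c) mean(cell == c), numeric(1))
  # start: impute cell means of observed values (overall mean fallback)
  Yc <- Y
  for (c in cells) {
    rows <- cell == c & mis
    if (any(rows)) {
      donor <- Y[cell == c & !mis, 1]
      Yc[rows, 1] <- if (length(donor)) mean(donor) else mean(Y[!mis, 1])
    }
  }
  mu <- lapply(cells, function(c) colMeans(Yc[cell == c, , drop = FALSE]))
  centered <- Yc
  for (i in seq_along(cells)) {
    rows <- cell == cells[i]
    centered[rows, ] <- sweep(Yc[rows, , drop = FALSE], 2, mu[[i]])
  }
  sigma <- crossprod(centered) / n
  loglik <- numeric(0)
  for (it in seq_len(max_iter)) {
    s22i <- solve(sigma[-1, -1, drop = FALSE])
    b <- drop(sigma[1, -1] %*% s22i)              # regression of y1 on y23
    v <- sigma[1, 1] - sum(b * sigma[1, -1])      # conditional variance
    # E-step: conditional means for missing index values
    for (i in seq_along(cells)) {
      rows <- which(cell == cells[i] & mis)
      if (length(rows)) {
        dev <- sweep(Y[rows, -1, drop = FALSE], 2, mu[[i]][-1])
        Yc[rows, 1] <- mu[[i]][1] + drop(dev %*% b)
      }
    }
    # observed-data log-likelihood at current parameters
    ll <- sum(log(p_cell)[match(cell, cells)])
    for (i in seq_along(cells)) {
      co <- which(cell == cells[i] & !mis)
      mo <- which(cell == cells[i] & mis)
      if (length(co)) {
        ll <- ll + sum(dmvnorm_log(Y[co, , drop = FALSE], mu[[i]], sigma))
      }
      if (length(mo)) {
        ll <- ll + sum(dmvnorm_log(Y[mo, -1, drop = FALSE], mu[[i]][-1],
                                   sigma[-1, -1, drop = FALSE]))
      }
    }
    loglik <- c(loglik, ll)
    # M-step
    mu <- lapply(cells, function(c) colMeans(Yc[cell == c, , drop = FALSE]))
    for (i in seq_along(cells)) {
      rows <- cell == cells[i]
      centered[rows, ] <- sweep(Yc[rows, , drop = FALSE], 2, mu[[i]])
    }
    sigma <- crossprod(centered) / n
    sigma[1, 1] <- sigma[1, 1] + v * sum(mis) / n   # E[y1^2] correction
    if (it > 1 && abs(loglik[it] - loglik[it - 1]) < tol) break
  }
  list(mu = mu, sigma = sigma, cells = cells, loglik = loglik)
}

#' Joint-model multiple imputation (general location model)
#'
#' Imputes missing index values under a general location model whose
#' categorical part is the (disease, binary covariate) cross-classification
#' and whose continuous part (index, cov_c1, cov_c2) is multivariate normal
#' with cell-specific means and a common covariance.  Parameters are first
#' estimated by EM on the incomplete data; `m` imputations are then drawn
#' by data augmentation (alternating imputation of the missing index values
#' with parameter draws from the normal / inverted-Wishart posterior under
#' a noninformative prior), with `burn_in` initial iterations discarded and
#' `thin` iterations between retained imputations.  Completed datasets are
#' pooled by Rubin's rules.
#'
#' An empty mixed cell collapses the categorical part to the disease groups
#' alone; the method fails only if the EM step cannot proceed (degenerate
#' covariance).
#'
#' @param data a `diagnostic_dataset`.
#' @param alpha two-sided significance level.
#' @param m number of imputations (default 20).
#' @param burn_in data augmentation burn-in iterations (default 200).
#' @param thin iterations between retained imputations (default 100).
#' @return an `auc_estimate`.
#' @export
estimate_mi_joint <- function(data, alpha = 0.05, m = 20L, burn_in = 200L,
                              thin = 100L) {
  g <- split_groups(data)
  if (all(g$obs)) {
    if (length(g$pos_obs) < 2L || length(g$neg_obs) < 2L) {
      return(failed_estimate("mi-joint",
                             "fewer than 2 subjects in a disease group"))
    }
    dl <- delong_ci(g$pos_obs, g$neg_obs, alpha)
    return(new_estimate("mi-joint", dl$auc, dl$se, dl$ci_lower, dl$ci_upper,
                        n_imputations = m))
  }
  Y <- cbind(data$index, data$cov_c1, data$cov_c2)
  cell <- data$disease * 2L + data$cov_bin
  if (length(unique(cell)) < 4L) cell <- data$disease  # collapse empty cells
  em <- tryCatch(glm_em(Y, cell),
                 error = function(e) NULL)
  if (is.null(em)) {
    return(failed_estimate("mi-joint", "EM for the general location model failed"))
  }
  cells <- em$cells
  n_cells <- length(cells)
  mu_mat <- do.call(rbind, em$mu)           # n_cells x 3
  sigma <- em$sigma
  n <- nrow(Y)
  cell_idx <- match(cell, cells)            # per-subject cell position
  n_c <- tabulate(cell_idx, n_cells)
  mis <- which(is.na(Y[, 1]))
  mis_cell <- cell_idx[mis]
  Y23_mis <- Y[mis, -1, drop = FALSE]       # fixed covariate block
  df <- n - n_cells
  Yc <- Y
  Yc[mis, 1] <- 0
  completed <- vector("list", m)
  kept <- 0L
  total_iter <- burn_in + (m - 1L) * thin + 1L
  D <- matrix(0, n, n_cells)                # cell indicator for fast means
  D[cbind(seq_len(n), cell_idx)] <- 1
  n_mis <- length(mis)
  for (it in seq_len(total_iter)) {
    # I-step: draw missing index values from their conditional normal
    s22 <- sigma[2:3, 2:3]
    det22 <- s22[1, 1] * s22[2, 2] - s22[1, 2] * s22[2, 1]
    b <- c(sigma[1, 2] * s22[2, 2] - sigma[1, 3] * s22[2, 1],
           sigma[1, 3] * s22[1, 1] - sigma[1, 2] * s22[1, 2]) / det22
    v <- max(sigma[1, 1] - b[1] * sigma[1, 2] - b[2] * sigma[1, 3], 1e-12)
    dev <- Y23_mis - mu_mat[mis_cell, -1, drop = FALSE]
    Yc[mis, 1] <- mu_mat[mis_cell, 1] + dev %*% b +
      sqrt(v) * stats::rnorm(n_mis)
    # P-step: draw (sigma, cell means) from the completed-data posterior
    ybar <- crossprod(D, Yc) / n_c
    centered <- Yc - D %*% ybar
    S <- crossprod(centered)
    sigma <- tryCatch(
      chol2inv(chol(stats::rWishart(1, df, chol2inv(chol(S)))[, , 1])),
      error = function(e) S / df)
    ch <- tryCatch(chol(sigma), error = function(e) NULL)
    mu_mat <- if (is.null(ch)) ybar else {
      ybar + (matrix(stats::rnorm(3 * n_cells), n_cells, 3) %*% ch) / sqrt(n_c)
    }
    if (it >= burn_in + 1L && (it - burn_in - 1L) %% thin == 0L) {
      kept <- kept + 1L
      completed[[kept]] <- Yc[, 1]
      if (kept == m) break
    }
  }
  pool_imputed_auc("mi-joint", data, completed, alpha)
}
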