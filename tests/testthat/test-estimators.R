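test_that("every estimator reduces to the complete-data AUC when nothing is missing", {
  d <- make_amputed(n = 80, pm = 0, seed = 7)
  full <- auc_trapezoid(d$index[d$disease == 1], d$index[d$disease == 0])
  for (m in available_methods()) {
    set.seed(9)
    e <- estimate_auc(d, m)
    expect_false(e$failed)
    tol <- if (m == "ker") 1 / 101 else 1e-9
    expect_lt(abs(e$auc - full), tol + 1e-12, label = m)
  }
})

test_that("estimates respect the AUC-estimate contract on random inputs", {
  set.seed(11)
  for (i in 1:6) {
    mech <- sample(c("MCAR", "MAR", "MNAR"), 1)
    d <- make_amputed(n = 120, p = 0.25, mech = mech, pm = 0.4,
                      seed = 500 + i)
    for (m in available_methods()) {
      e <- estimate_auc(d, m)
      expect_s3_class(e, "auc_estimate")
      if (e$failed) {
        expect_true(is.na(e$auc) && is.na(e$se) && is.na(e$ci_lower))
      } else {
        expect_true(e$auc >= 0 && e$auc <= 1, label = m)
        expect_true(e$ci_lower <= e$auc && e$auc <= e$ci_upper, label = m)
      }
    }
  }
})

test_that("CCA equals a hand recomputation after dropping known rows", {
  d <- build_dataset(rep(c(1, 0), c(5, 7)), c(3, 2.5, 4, 1, 5, 0, 1.5, 2, 2.6,
                                              0.5, 3.1, 1.1))
  d$index[c(2, 8, 11)] <- NA
  d$observed <- as.integer(!is.na(d$index))
  e <- estimate_cca(d)
  keep <- !is.na(d$index)
  expect_equal(e$auc, enum_auc(d$index[d$disease == 1 & keep],
                               d$index[d$disease == 0 & keep]))
})

test_that("estimators fail as a state, never as an error, on empty groups", {
  d <- make_amputed(n = 60, p = 0.2, pm = 0, seed = 13)
  d$index[d$disease == 1] <- NA
  d$observed <- as.integer(!is.na(d$index))
  for (m in c("cca", "aipw", "ker", "hdel", "mi-knn")) {
    e <- expect_no_error(estimate_auc(d, m))
    expect_true(e$failed, label = m)
    expect_match(e$failure_reason, ".")
  }
})

test_that("AIPW fails below its complete-case threshold but not above", {
  d <- make_amputed(n = 100, p = 0.1, pm = 0, seed = 17)
  pos_rows <- which(d$disease == 1)
  d$index[pos_rows[1:5]] <- NA  # 5 complete diseased cases remain
  d$observed <- as.integer(!is.na(d$index))
  e <- estimate_aipw(d, n_boot = 0)
  expect_true(e$failed)
  d2 <- make_amputed(n = 100, p = 0.1, pm = 0, seed = 17)
  d2$index[pos_rows[1:4]] <- NA  # 6 remain
  d2$observed <- as.integer(!is.na(d2$index))
  e2 <- estimate_aipw(d2, n_boot = 0)
  expect_false(e2$failed)
})

test_that("PMM imputes only observed donor values", {
  set.seed(19)
  yhat_obs <- rnorm(50)
  y_obs <- rnorm(50)
  imp <- aucmiss:::pmm_match(yhat_obs, y_obs, rnorm(30), donors = 5)
  expect_true(all(imp %in% y_obs))
  # single donor pool degenerates to that donor
  expect_identical(aucmiss:::pmm_match(0, 3.14, c(-1, 2), donors = 5),
                   c(3.14, 3.14))
})

test_that("chained-equation MI drops aliased columns but needs residual df", {
  d <- make_amputed(n = 80, pm = 0.3, seed = 23)
  d$cov_c2 <- d$cov_c1  # aliased covariates are dropped, not fatal
  set.seed(3)
  e <- estimate_mi_fcs(d, variant = "norm")
  expect_false(e$failed)
  # with no residual degrees of freedom the imputation model is hopeless
  d2 <- d[1:40, ]
  d2$index[-(1:4)] <- NA
  d2$observed <- as.integer(!is.na(d2$index))
  e2 <- estimate_mi_fcs(d2, variant = "pmm")
  expect_true(e2$failed)
  expect_match(e2$failure_reason, "complete cases")
})

test_that("kNN MI with a coincident donor imputes that donor's value", {
  # one missing diseased subject whose covariates coincide with exactly one
  # complete diseased case; all other diseased cases are far away in both
  # scores, so k = 1 must always select the coincident donor
  d <- build_dataset(
    disease = c(1, 1, 1, 1, 0, 0, 0, 0, 0),
    index = c(NA, 4, 9, 10, 1, 2, 3, 2.5, 1.5),
    cov_bin = c(1, 1, 0, 0, 1, 0, 1, 0, 1),
    cov_c1 = c(5, 5, 9, 9.5, 5, 6, 4, 5.5, 6.5),
    cov_c2 = c(35, 35, 40, 41, 35, 36, 34, 33, 37))
  set.seed(29)
  e <- estimate_mi_knn(d, k = 1, m = 5)
  completed <- d$index
  completed[1] <- 4  # the coincident donor's value
  expect_false(e$failed)
  expect_equal(e$auc, enum_auc(completed[d$disease == 1],
                               completed[d$disease == 0]))
})

test_that("label-swap antisymmetry holds for the deterministic estimators", {
  d <- make_amputed(n = 150, p = 0.3, mech = "MAR", pm = 0.3, seed = 31)
  swapped <- d
  swapped$index <- -d$index
  swapped$disease <- 1L - d$disease
  expect_equal(estimate_cca(swapped)$auc, estimate_cca(d)$auc)
  expect_equal(estimate_aipw(swapped, n_boot = 0)$auc,
               estimate_aipw(d, n_boot = 0)$auc, tolerance = 1e-10)
})

test_that("label-swap antisymmetry holds on average for imputation methods", {
  d <- make_amputed(n = 150, p = 0.3, mech = "MCAR", pm = 0.3, seed = 37)
  swapped <- d
  swapped$index <- -d$index
  swapped$disease <- 1L - d$disease
  for (m in c("hdel", "mi-pmm")) {
    a1 <- mean(vapply(1:25, function(i) {
      set.seed(1000 + i); estimate_auc(d, m)$auc
    }, numeric(1)))
    a2 <- mean(vapply(1:25, function(i) {
      set.seed(2000 + i); estimate_auc(swapped, m)$auc
    }, numeric(1)))
    expect_lt(abs(a1 - a2), 0.015, label = m)
  }
})

test_that("general location model EM has a nondecreasing log-likelihood", {
  set.seed(41)
  for (i in 1:5) {
    d <- make_amputed(n = 150, p = 0.3, mech = sample(c("MAR", "MNAR"), 1),
                      pm = 0.4, seed = 600 + i)
    Y <- cbind(d$index, d$cov_c1, d$cov_c2)
    cell <- d$disease * 2L + d$cov_bin
    em <- aucmiss:::glm_em(Y, cell)
    expect_true(all(diff(em$loglik) >= -1e-7))
    expect_gt(length(em$loglik), 2)
  }
})

test_that("HDEL interval contains its point estimate and degrades gracefully", {
  d <- make_amputed(n = 200, p = 0.3, pm = 0.3, seed = 43)
  set.seed(47)
  e <- estimate_hdel(d)
  expect_false(e$failed)
  expect_true(e$ci_lower <= e$auc && e$auc <= e$ci_upper)
  expect_true(is.na(e$ci_warning))
  # perfectly separated groups: placement values are degenerate
  d2 <- build_dataset(rep(c(1, 0), each = 5),
                      c(11:15, 1:5))
  e2 <- estimate_hdel(d2)
  expect_equal(e2$auc, 1)
  expect_false(is.na(e2$ci_warning))
})

test_that("the empirical likelihood ratio is calibrated at its bounds", {
  set.seed(53)
  v <- runif(60)
  ci <- aucmiss:::el_mean_ci(v, alpha = 0.05)
  expect_lt(ci$lower, mean(v))
  expect_gt(ci$upper, mean(v))
  crit <- qchisq(0.95, 1)
  expect_equal(aucmiss:::el_loglik_ratio(v, ci$lower), crit, tolerance = 1e-3)
  expect_equal(aucmiss:::el_loglik_ratio(v, ci$upper), crit, tolerance = 1e-3)
  expect_equal(aucmiss:::el_loglik_ratio(v, mean(v)), 0, tolerance = 1e-10)
})

test_that("KER attaches a weighted ROC and handles perfect separation", {
  d <- build_dataset(rep(c(1, 0), each = 6), c(7:12, 1:6))
  d$index[c(2, 8)] <- NA
  d$observed <- as.integer(!is.na(d$index))
  e <- estimate_ker(d)
  expect_false(e$failed)
  expect_equal(e$auc, 1)
  expect_s3_class(e$roc, "roc_curve")
})
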