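test_that("trapezoidal AUC equals exhaustive pair enumeration", {
  expect_equal(auc_trapezoid(c(1, 2), c(1, 2)), 0.5)
  expect_equal(auc_trapezoid(c(3, 1), c(2, 0)), 0.75)
  expect_equal(auc_trapezoid(c(5, 6), c(1, 2)), 1)
  set.seed(101)
  for (i in 1:100) {
    pos <- sample(0:8, sample(2:12, 1), replace = TRUE)  # ties guaranteed
    neg <- sample(0:8, sample(2:12, 1), replace = TRUE)
    expect_equal(auc_trapezoid(pos, neg), enum_auc(pos, neg))
  }
  expect_error(auc_trapezoid(numeric(0), 1:3), "nonempty")
})

test_that("AUC complement and monotone-transform invariance hold", {
  set.seed(102)
  for (i in 1:25) {
    pos <- rnorm(7, 1)
    neg <- c(rnorm(9), pos[1])  # inject a tie
    expect_equal(auc_trapezoid(pos, neg) + auc_trapezoid(neg, pos), 1)
    expect_equal(auc_trapezoid(exp(pos), exp(neg)), auc_trapezoid(pos, neg))
  }
})

test_that("DeLong variance matches brute-force structural components", {
  pos <- c(3, 1); neg <- c(2, 0)
  dl <- delong_ci(pos, neg)
  expect_equal(dl$auc, 0.75)
  expect_equal(dl$se, enum_delong_se(pos, neg))
  set.seed(103)
  for (i in 1:20) {
    pos <- rnorm(sample(3:20, 1), 1)
    neg <- rnorm(sample(3:20, 1))
    dl <- delong_ci(pos, neg)
    expect_equal(dl$se, enum_delong_se(pos, neg))
    expect_equal(dl$ci_upper - dl$auc, qnorm(0.975) * dl$se)
  }
  expect_error(delong_ci(1, c(0, 2)), "at least 2")
})

test_that("DeLong AUC, variance and CI agree with pROC", {
  skip_if_not_installed("pROC")
  set.seed(104)
  pos <- rnorm(40, 1.2)
  neg <- rnorm(60)
  dl <- delong_ci(pos, neg)
  r <- pROC::roc(response = rep(c(1, 0), c(40, 60)), predictor = c(pos, neg),
                 direction = "<", quiet = TRUE)
  expect_equal(dl$auc, as.numeric(pROC::auc(r)), tolerance = 1e-12)
  expect_equal(dl$se, sqrt(pROC::var(r)), tolerance = 1e-10)
  ci <- as.numeric(pROC::ci.auc(r, method = "delong"))
  expect_equal(dl$ci_lower, ci[1], tolerance = 1e-10)
  expect_equal(dl$ci_upper, ci[3], tolerance = 1e-10)
})

test_that("perfect separation gives zero DeLong variance and a point CI", {
  dl <- delong_ci(c(5, 6, 7), c(1, 2, 3))
  expect_equal(dl$auc, 1)
  expect_equal(dl$se, 0)
  expect_equal(c(dl$ci_lower, dl$ci_upper), c(1, 1))
})

test_that("DeLong se tracks the bootstrap se of the AUC", {
  set.seed(105)
  pos <- rnorm(100, mu_from_auc(0.85))
  neg <- rnorm(100)
  dl <- delong_ci(pos, neg)
  boot <- replicate(2000, {
    auc_trapezoid(sample(pos, replace = TRUE), sample(neg, replace = TRUE))
  })
  expect_lt(abs(dl$se - sd(boot)) / sd(boot), 0.2)
})

test_that("Hanley-McNeil se matches hand evaluation", {
  # theta = 0.5: Q1 = Q2 = 1/3, se^2 = (0.25 + 18 * (1/3 - 0.25)) / 100
  expect_equal(hanley_mcneil_se(0.5, 10, 10), sqrt(0.0175))
  th <- 0.8
  q1 <- th / (2 - th); q2 <- 2 * th^2 / (1 + th)
  manual <- sqrt((th * (1 - th) + 49 * (q1 - th^2) + 49 * (q2 - th^2)) / 2500)
  expect_equal(hanley_mcneil_se(0.8, 50, 50), manual)
  expect_lt(hanley_mcneil_se(0.5, 1e6, 1e6), 1e-3)
  expect_warning(se1 <- hanley_mcneil_se(1, 10, 10), "degenerate")
  expect_identical(se1, 0)
})

test_that("empirical ROC curves have the right endpoints, area, invariances", {
  r <- empirical_roc(c(2, 3), c(0, 1))
  expect_equal(r$fpr[1], 0)
  expect_equal(r$tpr[1], 0)
  expect_equal(utils::tail(r$fpr, 1), 1)
  expect_equal(utils::tail(r$tpr, 1), 1)
  expect_true(any(r$fpr == 0 & r$tpr == 1))  # passes through (0, 1)
  expect_equal(roc_area(r), 1)
  set.seed(106)
  for (i in 1:50) {
    pos <- sample(0:6, 8, replace = TRUE)
    neg <- sample(0:6, 11, replace = TRUE)
    rr <- empirical_roc(pos, neg)
    expect_true(all(diff(rr$fpr) >= 0))
    expect_true(all(diff(rr$tpr) >= 0))
    expect_equal(roc_area(rr), auc_trapezoid(pos, neg))
  }
  w <- runif(8); v <- runif(11)
  r1 <- empirical_roc(pos, neg, w, v)
  r2 <- empirical_roc(pos, neg, 2 * w, 2 * v)
  expect_equal(r1, r2)
  expect_error(empirical_roc(pos, neg, rep(0, 8), v), "all zero")
})

test_that("Rubin's rules pool point estimates and variances correctly", {
  p <- rubin_pool(c(0.8, 0.8, 0.8), rep(0.01, 3))
  expect_equal(p$pooled, 0.8)
  expect_equal(p$se^2, 0.01)           # B = 0 collapses to W
  expect_identical(p$df, Inf)

  p2 <- rubin_pool(c(0.7, 0.9), c(0.01, 0.01))
  expect_equal(p2$pooled, 0.8)
  expect_equal(p2$se^2, 0.01 + 1.5 * 0.02)  # W + (1 + 1/m) B = 0.04
  expect_equal(p2$df, (1 + 0.01 / 0.03)^2)  # classical Rubin df
  expect_equal(p2$ci_lower, 0.8 - qt(0.975, p2$df) * 0.2)

  p1 <- rubin_pool(0.73, 0.02)
  expect_equal(p1$pooled, 0.73)
  expect_equal(p1$se^2, 0.02)
  expect_error(rubin_pool(numeric(0), numeric(0)))
})
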