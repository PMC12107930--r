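make_summaries <- function(method = "cca", bias_fun = function(g) 0,
                           rmse_fun = function(g) 0.05) {
  g <- scenario_grid()
  g$method <- method
  g$bias <- bias_fun(g)
  g$rmse <- rmse_fun(g)
  g
}

test_that("a pure linear signal is recovered with all other terms eliminated", {
  # a whisper of noise keeps the AIC comparisons well defined
  set.seed(69)
  s <- make_summaries(bias_fun = function(g) {
    (2 + 3 * g$prop_missing + rnorm(nrow(g), 0, 1e-6)) / 100
  })
  f <- fit_ols_metamodel(s[s$mechanism == "MAR", ], "bias", "MAR", "cca")
  co <- f$coefficients
  expect_equal(unname(co["(Intercept)"]), 2, tolerance = 1e-4)
  expect_equal(unname(co["prop_missing"]), 3, tolerance = 1e-4)
  # any spurious term that survives AIC elimination is numerically nil
  spurious <- co[setdiff(names(co), c("(Intercept)", "prop_missing"))]
  if (length(spurious)) expect_lt(max(abs(spurious)), 1e-3)
  expect_gt(f$r_squared, 0.999)
})

test_that("a planted interaction is retained together with its main effects", {
  set.seed(71)
  s <- make_summaries(bias_fun = function(g) {
    (5 * g$prevalence * g$correlation + rnorm(nrow(g), 0, 0.02)) / 100
  })
  f <- fit_ols_metamodel(s[s$mechanism == "MCAR", ], "bias", "MCAR", "cca")
  nm <- names(f$coefficients)
  expect_true("prevalence:correlation" %in% nm)
  expect_true(all(c("prevalence", "correlation") %in% nm))
})

test_that("backward elimination preserves the model hierarchy", {
  set.seed(73)
  for (i in 1:10) {
    s <- make_summaries(bias_fun = function(g) rnorm(nrow(g), 0, 0.01) +
                          i * 0.001 * g$prevalence * g$auc_true)
    f <- fit_ols_metamodel(s[s$mechanism == "MNAR", ], "bias", "MNAR", "cca")
    nm <- setdiff(names(f$coefficients), "(Intercept)")
    inter <- nm[grepl(":", nm)]
    mains <- unique(unlist(strsplit(inter, ":")))
    expect_true(all(mains %in% nm))
  }
})

test_that("pure noise rarely retains a large model", {
  set.seed(79)
  n_terms <- replicate(40, {
    s <- make_summaries(bias_fun = function(g) rnorm(nrow(g), 0, 0.01))
    f <- fit_ols_metamodel(s[s$mechanism == "MCAR", ], "bias", "MCAR", "cca")
    length(setdiff(names(f$coefficients), "(Intercept)"))
  })
  # AIC-based elimination keeps the occasional spurious term but the
  # retained models stay small and explain essentially nothing
  expect_lt(median(n_terms), 5)
  expect_lt(mean(n_terms), 15 / 2)
})

test_that("the stratum size precondition is enforced", {
  s <- make_summaries()[1:10, ]
  expect_error(fit_ols_metamodel(s, "bias", s$mechanism[1], "cca"),
               "at least 30")
})

make_mixed_summaries <- function(offsets, scen_sd = 0.03, noise_sd = 0.005,
                                 seed = 81) {
  set.seed(seed)
  g <- scenario_grid(mechanism = "MAR")
  scen_eff <- rnorm(nrow(g), 0, scen_sd)
  out <- do.call(rbind, lapply(names(offsets), function(m) {
    gg <- g
    gg$method <- m
    gg$bias <- (offsets[[m]] + scen_eff + rnorm(nrow(g), 0, noise_sd))
    gg$rmse <- abs(gg$bias)
    gg
  }))
  out
}

test_that("the mixed metamodel recovers a planted method offset", {
  # biases are kept away from zero so the absolute-value transform of the
  # outcome is the identity and the contrast is exactly the planted 0.05
  s <- make_mixed_summaries(list(cca = 0.1, `mi-pmm` = 0.15), scen_sd = 0.01)
  f <- fit_mixed_metamodel(s, "bias", "MAR")
  co <- f$coefficients
  expect_equal(unname(co[grep("^methodmi.pmm$", names(co))]), 5,
               tolerance = 0.3)
  expect_false(f$singular_refit)
})

test_that("identical methods give near-zero method contrasts and the random
           intercept absorbs the scenario variance", {
  s <- make_mixed_summaries(list(cca = 0.1, hdel = 0.1, ker = 0.1),
                            scen_sd = 0.03, noise_sd = 0.005)
  f <- fit_mixed_metamodel(s, "bias", "MAR")
  co <- f$coefficients
  meth_co <- co[grep("^method", names(co))]
  meth_co <- meth_co[!grepl(":", names(meth_co))]
  expect_true(all(abs(meth_co) < 0.5))
  vc <- as.data.frame(lme4::VarCorr(f$model))
  ri_sd <- vc$sdcor[vc$grp == "scenario"]
  resid_sd <- vc$sdcor[vc$grp == "Residual"]
  expect_gt(ri_sd, resid_sd)
})

test_that("dropping the random intercept inflates the residual variance", {
  s <- make_mixed_summaries(list(cca = 0.1, hdel = 0.12), scen_sd = 0.05,
                            noise_sd = 0.01, seed = 83)
  f <- fit_mixed_metamodel(s, "bias", "MAR")
  lm_fit <- lm(100 * abs(bias) ~ method + prop_missing, data = s)
  vc <- as.data.frame(lme4::VarCorr(f$model))
  resid_mixed <- vc$sdcor[vc$grp == "Residual"]
  expect_gt(summary(lm_fit)$sigma, resid_mixed)
})
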