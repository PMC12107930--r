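# Metamodels: regressions of scenario-level performance measures on the
# simulation parameters, quantifying which parameters drive a method's
# bias or RMSE.  Outcomes are scaled by 100 for interpretable coefficients;
# bias enters as its absolute value.

metamodel_outcome <- function(summaries, outcome = c("bias", "rmse")) {
  outcome <- match.arg(outcome)
  y <- if (outcome == "bias") abs(summaries$bias) else summaries$rmse
  100 * y
}

#' Per-method linear metamodel with backward elimination
#'
#' Fits, within one missingness-mechanism stratum and for one method, an
#' ordinary least squares regression of a performance measure (x100; bias
#' as absolute value) on the simulation parameters `n_total`, `prevalence`,
#' `correlation`, `auc_true`, `prop_missing` and all their two-way
#' interactions, then removes terms by AIC-based backward elimination.
#' Elimination respects the model hierarchy: a main effect is never removed
#' while a retained interaction contains it.
#'
#' @param summaries scenario-level summaries from [summarize_results()].
#' @param outcome `"bias"` (absolute bias) or `"rmse"`.
#' @param mechanism mechanism stratum to fit in ("MCAR", "MAR" or "MNAR").
#' @param method method identifier to fit for.
#' @return object of class `metamodel_fit`: retained coefficients, R
#'   squared, the fitted `lm`.
#' @export
fit_ols_metamodel <- function(summaries, outcome = c("bias", "rmse"),
                              mechanism, method) {
  outcome <- match.arg(outcome)
  d <- summaries[summaries$mechanism == mechanism &
                   summaries$method == method, ]
  if (nrow(d) < 30L) {
    stop("need at least 30 scenario-level rows in the stratum", call. = FALSE)
  }
  d$y <- metamodel_outcome(d, outcome)
  full <- stats::lm(
    y ~ (n_total + prevalence + correlation + auc_true + prop_missing)^2,
    data = d)
  # drop aliased interaction terms before elimination (rank deficiency)
  if (anyNA(stats::coef(full))) {
    warning("rank-deficient design: dropping aliased terms")
    keep <- names(stats::coef(full))[!is.na(stats::coef(full))]
    keep <- setdiff(keep, "(Intercept)")
    full <- stats::lm(stats::reformulate(gsub(":", ":", keep), response = "y"),
                      data = d)
  }
  red <- stats::step(full, direction = "backward", trace = 0)
  structure(
    list(outcome = outcome, mechanism = mechanism, method = method,
         approach = "per-method OLS",
         coefficients = stats::coef(red),
         r_squared = summary(red)$r.squared,
         model = red),
    class = "metamodel_fit")
}

#' All-methods mixed-model metamodel
#'
#' Fits, within one mechanism stratum, a linear mixed model of a
#' performance measure (x100) on method indicators (reference: complete
#' case analysis), the simulation parameters, and method x parameter
#' interactions, with a scenario-level random intercept.  Interactions are
#' removed by AIC-based backward elimination (main effects are retained).
#' If the random-intercept variance is estimated as singular, the model is
#' refitted without the random intercept and flagged.
#'
#' @param summaries scenario-level summaries from [summarize_results()]
#'   covering at least two methods per scenario.
#' @param outcome `"bias"` (absolute bias) or `"rmse"`.
#' @param mechanism mechanism stratum.
#' @return object of class `metamodel_fit` with fixed-effect coefficients,
#'   marginal R squared, the fitted model, and `singular_refit` flag.
#' @export
fit_mixed_metamodel <- function(summaries, outcome = c("bias", "rmse"),
                                mechanism) {
  outcome <- match.arg(outcome)
  d <- summaries[summaries$mechanism == mechanism, ]
  if (length(unique(d$method)) < 2L) {
    stop("need scenario-level rows for at least 2 methods", call. = FALSE)
  }
  d$y <- metamodel_outcome(d, outcome)
  d$method <- stats::relevel(factor(d$method),
                             ref = if ("cca" %in% d$method) "cca"
                                   else levels(factor(d$method))[1])
  d$scenario <- factor(d$scenario_id)
  params <- c("n_total", "prevalence", "correlation", "auc_true",
              "prop_missing")
  present <- params[vapply(params, function(p) length(unique(d[[p]])) > 1L,
                           logical(1))]
  inter <- paste0("method:", present)
  fixed_terms <- c("method", present, inter)
  fit_with <- function(terms, random = TRUE) {
    fo <- stats::reformulate(c(terms, if (random) "(1 | scenario)"),
                             response = "y")
    if (random) {
      lme4::lmer(fo, data = d, REML = FALSE)
    } else {
      stats::lm(fo, data = d)
    }
  }
  singular_refit <- FALSE
  fit <- fit_with(fixed_terms)
  if (lme4::isSingular(fit)) {
    singular_refit <- TRUE
    warning("singular random-intercept variance: refitting without it")
  }
  refit <- function(terms) if (singular_refit) fit_with(terms, FALSE)
                           else fit_with(terms)
  fit <- refit(fixed_terms)
  # backward elimination over the method x parameter interactions only
  terms <- fixed_terms
  repeat {
    cur_inter <- intersect(terms, inter)
    if (!length(cur_inter)) break
    aic0 <- stats::AIC(fit)
    cand <- lapply(cur_inter, function(tm) refit(setdiff(terms, tm)))
    aics <- vapply(cand, stats::AIC, numeric(1))
    if (min(aics) >= aic0) break
    best <- which.min(aics)
    terms <- setdiff(terms, cur_inter[best])
    fit <- cand[[best]]
  }
  coefs <- if (singular_refit) stats::coef(fit) else lme4::fixef(fit)
  # marginal R^2: variance of the fixed-effect predictions over total
  pred <- if (singular_refit) stats::fitted(fit) else {
    drop(stats::model.matrix(fit) %*% coefs)
  }
  r2_marg <- stats::var(pred) / stats::var(d$y)
  structure(
    list(outcome = outcome, mechanism = mechanism, method = "all",
         approach = "all-methods mixed", coefficients = coefs,
         r_squared = r2_marg, model = fit,
         singular_refit = singular_refit),
    class = "metamodel_fit")
}

#' @export
print.metamodel_fit <- function(x, ...) {
  cat(sprintf("metamodel (%s) for %s, mechanism %s, outcome %s x 100\n",
              x$approach, x$method, x$mechanism, x$outcome))
  cat(sprintf("fit statistic (R squared): %.3f\n", x$r_squared))
  print(round(x$coefficients, 4))
  invisible(x)
}
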