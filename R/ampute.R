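# Amputation: inducing missing values in the index test of a complete
# cohort under MCAR, MAR or MNAR, following multivariate-amputation
# semantics: a weighted sum score of the data determines each subject's
# missingness probability.

#' Per-subject missingness scores
#'
#' Builds the weighted sum score that drives score-based amputation.
#' Under MCAR all subjects get the constant score 0 (equal probability);
#' under MAR the score is the sum of the three standardized covariates
#' (index weight 0); under MNAR it is the standardized index test itself
#' (covariate weights 0).  The binary covariate enters as standardized 0/1.
#'
#' @param data a complete `diagnostic_dataset` (no missing index values).
#' @param mechanism "MCAR", "MAR" or "MNAR".
#' @return numeric vector of length `nrow(data)`.
#' @export
missingness_scores <- function(data, mechanism = c("MCAR", "MAR", "MNAR")) {
  mechanism <- match.arg(mechanism)
  validate_dataset(data)
  if (anyNA(data$index)) {
    stop("missingness scores require a complete index test", call. = FALSE)
  }
  switch(mechanism,
    MCAR = rep(0, nrow(data)),
    MAR = standardize(data$cov_bin) + standardize(data$cov_c1) +
      standardize(data$cov_c2),
    MNAR = standardize(data$index)
  )
}

#' Ampute the index test
#'
#' Removes index test values from a complete cohort.  Under MCAR exactly
#' `round(n * pm)` values are removed uniformly at random.  Under MAR and
#' MNAR each subject is removed independently with probability
#' `plogis(z_i + b)` (type `"RIGHT"`: high scores preferentially missing) or
#' `plogis(-abs(z_i) + b)` (type `"MID"`: mid-range scores preferentially
#' missing), where `z_i` is the standardized missingness score and the
#' intercept `b` is solved numerically so that the mean removal probability
#' equals `pm` (to within 1e-10).  Only the index test is ever amputed.
#'
#' @param data a complete `diagnostic_dataset`.
#' @param mechanism "MCAR", "MAR" or "MNAR".
#' @param pm proportion of missing values in `[0, 1)`.
#' @param type amputation type, "RIGHT" (default) or "MID"; ignored for MCAR.
#' @return the dataset with amputed `index` and updated `observed` flag.
#' @export
#' @examples
#' set.seed(7)
#' d <- simulate_cohort(scenario_config(100, 0.3, 0.85, 0.5, "MNAR", 0.3))
#' a <- ampute_index(d, "MNAR", 0.3)
#' mean(is.na(a$index))
ampute_index <- function(data, mechanism = c("MCAR", "MAR", "MNAR"), pm,
                         type = c("RIGHT", "MID")) {
  mechanism <- match.arg(mechanism)
  type <- match.arg(type)
  stop_if_not_prob(pm, "pm")
  validate_dataset(data)
  if (anyNA(data$index)) stop("dataset already contains missing index values",
                              call. = FALSE)
  if (pm == 0) return(data)
  n <- nrow(data)
  if (mechanism == "MCAR") {
    drop_idx <- sample.int(n, round(n * pm))
  } else {
    z <- standardize(missingness_scores(data, mechanism))
    lin <- if (type == "RIGHT") z else -abs(z)
    f <- function(b) mean(stats::plogis(lin + b)) - pm
    b <- tryCatch(
      stats::uniroot(f, interval = c(-60, 60), tol = 1e-12)$root,
      error = function(e) stop("amputation intercept search failed: ",
                               conditionMessage(e), call. = FALSE))
    if (abs(f(b)) > 1e-8) {
      stop(sprintf("amputation calibration residual %.2e exceeds 1e-8", f(b)),
           call. = FALSE)
    }
    drop_idx <- which(stats::runif(n) < stats::plogis(lin + b))
  }
  data$index[drop_idx] <- NA_real_
  data$observed <- as.integer(!is.na(data$index))
  data
}
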