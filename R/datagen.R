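# Cohort simulation for a cross-sectional single-test diagnostic accuracy
# study: binary reference standard, one continuous index test, and three
# covariates with an exchangeable correlation structure.

#' Diseased-group mean of the index test for a target AUC
#'
#' Under the equal-variance binormal model (non-diseased index values
#' standard normal, diseased values shifted by `mu`), the AUC equals
#' `pnorm(mu / sqrt(2))`.  This returns the inverse map
#' `mu = qnorm(auc_true) * sqrt(2)`.
#'
#' @param auc_true target AUC in `[0.5, 1)`.
#' @return the diseased-group mean shift (non-negative real).
#' @export
#' @examples
#' mu_from_auc(0.5)   # 0
#' pnorm(mu_from_auc(0.85) / sqrt(2))  # 0.85
mu_from_auc <- function(auc_true) {
  if (!is.numeric(auc_true) || any(!is.finite(auc_true)) ||
      any(auc_true < 0.5) || any(auc_true >= 1)) {
    stop("'auc_true' must lie in [0.5, 1)", call. = FALSE)
  }
  stats::qnorm(auc_true) * sqrt(2)
}

#' Scenario configuration for the factorial simulation design
#'
#' Bundles and validates one cell of the simulation design: sample size,
#' prevalence, true AUC, exchangeable correlation between the index test and
#' the covariates, missingness mechanism, proportion of missing index values,
#' and the amputation type for the score-based mechanisms.
#'
#' The diseased-group size is `n_total * prevalence`.  For the factorial grid
#' this product is an integer by construction; non-integer products are
#' rounded to the nearest integer with a warning.  The exchangeable
#' correlation must exceed -1/3 so that the 4x4 correlation matrix is
#' positive definite.
#'
#' @param n_total total number of subjects.
#' @param prevalence proportion of subjects with the target condition, in (0,1).
#' @param auc_true true AUC in `[0.5, 1)`.
#' @param correlation exchangeable correlation `r` in (-1/3, 1).
#' @param mechanism missingness mechanism: "MCAR", "MAR" or "MNAR".
#' @param prop_missing proportion of index values to ampute, in `[0, 1)`.
#' @param mnar_type amputation type for the score-based mechanisms:
#'   "RIGHT" (high scores preferentially removed) or "MID" (mid-range scores).
#' @param n_reps number of simulation repetitions the scenario is run for.
#' @param seed integer seed associated with the scenario.
#' @return an object of class `scenario_config` (a named list).
#' @export
#' @examples
#' scenario_config(100, 0.1, 0.85, 0.5, "MNAR", 0.5)
scenario_config <- function(n_total, prevalence, auc_true, correlation,
                            mechanism = c("MCAR", "MAR", "MNAR"),
                            prop_missing = 0, mnar_type = c("RIGHT", "MID"),
                            n_reps = 1000L, seed = 1L) {
  mechanism <- match.arg(mechanism)
  mnar_type <- match.arg(mnar_type)
  stopifnot(is.numeric(n_total), length(n_total) == 1L, n_total >= 2)
  stop_if_not_prob(prop_missing, "prop_missing")
  if (prevalence <= 0 || prevalence >= 1) {
    stop("'prevalence' must lie in (0, 1)", call. = FALSE)
  }
  mu_from_auc(auc_true)  # validates range
  if (correlation <= -1 / 3 || correlation >= 1) {
    stop("'correlation' must lie in (-1/3, 1) for a positive definite ",
         "exchangeable correlation matrix", call. = FALSE)
  }
  n_dis <- n_total * prevalence
  if (abs(n_dis - round(n_dis)) > 1e-8) {
    warning(sprintf("n_total * prevalence = %.3f is not an integer; rounding to %d",
                    n_dis, round(n_dis)))
  }
  n_dis <- as.integer(round(n_dis))
  if (n_dis < 1L || n_dis >= n_total) {
    stop("rounded diseased-group size must lie strictly between 0 and n_total",
         call. = FALSE)
  }
  structure(
    list(n_total = as.integer(n_total), prevalence = prevalence,
         auc_true = auc_true, correlation = correlation,
         mechanism = mechanism, prop_missing = prop_missing,
         mnar_type = mnar_type, n_diseased = n_dis,
         n_reps = as.integer(n_reps), seed = as.integer(seed)),
    class = "scenario_config"
  )
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf(
    "scenario: N=%d, p=%.2f, AUC=%.2f, r=%.2f, %s pm=%.2f (%s), reps=%d, seed=%d\n",
    x$n_total, x$prevalence, x$auc_true, x$correlation, x$mechanism,
    x$prop_missing, x$mnar_type, x$n_reps, x$seed))
  invisible(x)
}

#' Simulate a complete diagnostic cohort
#'
#' Draws, separately within the diseased and non-diseased groups, the index
#' test `x1` and three covariates from a 4-variate normal distribution with
#' unit variances and exchangeable correlation `r`.  Means are
#' `(mu, 0, 5, 35)` in the diseased group and `(0, 0, 5, 35)` in the
#' non-diseased group, where `mu = qnorm(auc_true) * sqrt(2)`.  The second
#' variable is dichotomized at its population mean 0 to give the binary
#' covariate.  Covariate means do not depend on disease status, so the
#' covariates carry information about the index test only through `r`.
#'
#' The returned object is a `data.frame` of class `diagnostic_dataset` with
#' columns `id`, `disease` (1 = target condition present), `index` (possibly
#' `NA` after amputation), `cov_bin`, `cov_c1`, `cov_c2`, and `observed`
#' (1 = index value present).  Randomness is taken from the current R random
#' stream; call [set.seed()] (for example with [substream_seed()]) beforehand
#' for reproducibility.
#'
#' @param config a [scenario_config()] object.
#' @return a `diagnostic_dataset` with `n_total` rows, diseased rows first.
#' @export
#' @examples
#' set.seed(1)
#' d <- simulate_cohort(scenario_config(100, 0.1, 0.85, 0.5, "MCAR", 0.3))
#' table(d$disease)
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  r <- config$correlation
  sigma <- matrix(r, 4, 4)
  diag(sigma) <- 1
  mu_d <- mu_from_auc(config$auc_true)
  n_d <- config$n_diseased
  n_n <- config$n_total - n_d
  xd <- MASS::mvrnorm(n_d, mu = c(mu_d, 0, 5, 35), Sigma = sigma)
  xn <- MASS::mvrnorm(n_n, mu = c(0, 0, 5, 35), Sigma = sigma)
  if (n_d == 1L) xd <- matrix(xd, nrow = 1L)
  if (n_n == 1L) xn <- matrix(xn, nrow = 1L)
  x <- rbind(xd, xn)
  out <- data.frame(
    id = seq_len(config$n_total),
    disease = rep(c(1L, 0L), c(n_d, n_n)),
    index = x[, 1],
    cov_bin = as.integer(x[, 2] > 0),
    cov_c1 = x[, 3],
    cov_c2 = x[, 4],
    observed = 1L
  )
  class(out) <- c("diagnostic_dataset", "data.frame")
  out
}

# validate the diagnostic_dataset contract; returns the data invisibly
validate_dataset <- function(data) {
  need <- c("disease", "index", "cov_bin", "cov_c1", "cov_c2")
  if (!all(need %in% names(data))) {
    stop("dataset must contain columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(data$observed)) data$observed <- as.integer(!is.na(data$index))
  if (any((data$observed == 1L) != !is.na(data$index))) {
    stop("'observed' flag inconsistent with missing index values", call. = FALSE)
  }
  if (!all(data$disease %in% c(0L, 1L))) {
    stop("'disease' must be binary 0/1", call. = FALSE)
  }
  invisible(data)
}

#' Write / read a cohort as CSV
#'
#' Plain-text interchange format with header columns
#' `id, disease, index, cov_bin, cov_c1, cov_c2`; a missing index value is
#' stored as an empty field.
#'
#' @param data a `diagnostic_dataset`.
#' @param path file path.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()` returns
#'   a `diagnostic_dataset` with the `observed` flag reconstructed.
#' @export
write_cohort <- function(data, path) {
  validate_dataset(data)
  utils::write.csv(
    data[, c("id", "disease", "index", "cov_bin", "cov_c1", "cov_c2")],
    path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  d <- utils::read.csv(path)
  d$observed <- as.integer(!is.na(d$index))
  class(d) <- c("diagnostic_dataset", "data.frame")
  validate_dataset(d)
  d
}
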