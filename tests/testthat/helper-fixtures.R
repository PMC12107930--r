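# Shared fixtures and independent oracles for the test suite.

# brute-force AUC by exhaustive pair enumeration (independent of the
# placement-value implementation)
enum_auc <- function(pos, neg) {
  s <- 0
  for (p in pos) for (n in neg) {
    s <- s + (p > n) + 0.5 * (p == n)
  }
  s / (length(pos) * length(neg))
}

# brute-force DeLong structural components by double loops
enum_delong_se <- function(pos, neg) {
  nd <- length(pos); nn <- length(neg)
  v10 <- vapply(pos, function(p) mean((p > neg) + 0.5 * (p == neg)), numeric(1))
  v01 <- vapply(neg, function(n) mean((pos > n) + 0.5 * (pos == n)), numeric(1))
  sqrt(var(v10) / nd + var(v01) / nn)
}

# small hand-built diagnostic dataset
build_dataset <- function(disease, index, cov_bin = NULL, cov_c1 = NULL,
                          cov_c2 = NULL) {
  n <- length(disease)
  d <- data.frame(
    id = seq_len(n), disease = as.integer(disease), index = index,
    cov_bin = cov_bin %||% rep(c(0L, 1L), length.out = n),
    cov_c1 = cov_c1 %||% seq(4, 6, length.out = n),
    cov_c2 = cov_c2 %||% seq(34, 36, length.out = n),
    observed = as.integer(!is.na(index)))
  class(d) <- c("diagnostic_dataset", "data.frame")
  d
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# standard amputed cohort for estimator tests
make_amputed <- function(n = 200, p = 0.3, auc = 0.85, r = 0.5,
                         mech = "MCAR", pm = 0.3, seed = 42) {
  set.seed(seed)
  cfg <- scenario_config(n, p, auc, r, mech, pm)
  ampute_index(simulate_cohort(cfg), mech, pm)
}

# mean bias of a method over replicated scenario draws (shared data stream
# across methods via substream seeding)
replicate_bias <- function(method, n, p, auc, r, mech, pm, reps,
                           root_seed = 2024, ...) {
  vals <- numeric(0)
  for (i in seq_len(reps)) {
    set.seed(substream_seed(root_seed, i))
    cfg <- scenario_config(n, p, auc, r, mech, pm)
    d <- ampute_index(simulate_cohort(cfg), mech, pm)
    set.seed(substream_seed(root_seed, i, aucmiss:::method_key(method)))
    e <- estimate_auc(d, method, ...)
    if (!e$failed) vals <- c(vals, e$auc)
  }
  list(bias = mean(vals) - auc, n_ok = length(vals), values = vals)
}
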