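# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible substream seed
#'
#' Folds one or more non-negative integers into a root seed with a
#' linear-congruential mix, so that every (scenario, repetition, method)
#' combination owns an independent, re-derivable random stream.  All
#' arithmetic stays below 2^53 so the result is exact in double precision,
#' and the returned value is a valid 32-bit seed for [set.seed()].
#'
#' @param seed integer root seed.
#' @param ... further non-negative integer keys, folded in order.
#' @return a single integer in `[0, 2147483562]`.
#' @export
#' @examples
#' substream_seed(1, 3, 12)
substream_seed <- function(seed, ...) {
  s <- as.double(seed) %% 2147483563
  for (x in c(...)) {
    s <- (s * 69069 + as.double(x) * 41213 + 1) %% 2147483563
  }
  as.integer(s)
}

# hash a method id into a small integer key for seed derivation
method_key <- function(method) {
  sum(utf8ToInt(as.character(method)) * seq_len(nchar(method))) %% 100000
}

# standardize to mean 0 / sd 1; constant vectors map to all zeros
standardize <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

stop_if_not_prob <- function(x, name, open_upper = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 &&
    (if (open_upper) x < 1 else x <= 1)
  if (!ok) stop(sprintf("'%s' must be a single number in [0, 1%s",
                        name, if (open_upper) ")" else "]"), call. = FALSE)
  invisible(x)
}

# Ridge-penalized logistic regression via IRLS.  glm() raises warnings and
# unstable fits near separation; the tiny ridge keeps the normal equations
# solvable and lets callers turn separation into a failure *state*.
ridge_logistic <- function(X, y, lambda = 1e-8, maxit = 50, tol = 1e-10) {
  p <- ncol(X)
  beta <- numeric(p)
  dev_old <- Inf
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    XtW <- t(X * w)
    beta_new <- tryCatch(
      solve(XtW %*% X + diag(lambda, p), XtW %*% z),
      error = function(e) NULL
    )
    if (is.null(beta_new)) {
      return(list(coef = beta, fitted = mu, converged = FALSE, separated = TRUE))
    }
    beta <- drop(beta_new)
    mu <- stats::plogis(drop(X %*% beta))
    mu_c <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    dev <- -2 * sum(y * log(mu_c) + (1 - y) * log(1 - mu_c))
    if (abs(dev - dev_old) < tol) break
    dev_old <- dev
  }
  separated <- max(abs(drop(X %*% beta))) > 30
  list(coef = beta, fitted = stats::plogis(drop(X %*% beta)),
       converged = TRUE, separated = separated)
}
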