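# Exact and classical tests for the two-alternative choice assays.

#' Exact binomial proportion test
#'
#' Two-sided exact binomial test of `k` successes in `n` trials against a
#' null proportion, with the minimum-likelihood two-sided p-value (the sum of
#' the probabilities of all outcomes no more likely than the observed one; at
#' `p_null = 0.5` this equals the doubled one-tail probability capped at 1)
#' and an exact Clopper-Pearson 95% interval on the proportion. The interval
#' bars drawn in figure summaries of such assays are sometimes labeled
#' "credible intervals"; a Jeffreys posterior interval is available via
#' `interval = "jeffreys"` (the p-value is unaffected by the choice).
#'
#' @param k Number of successes (e.g. social selections).
#' @param n Number of trials with a choice.
#' @param p_null Null proportion, strictly between 0 and 1.
#' @param interval `"clopper-pearson"` (exact, default) or `"jeffreys"`
#'   (equal-tailed Beta(1/2, 1/2) posterior interval).
#' @param conf_level Interval coverage (default 0.95).
#' @return A `binomial_result` list: `k`, `n`, `p_null`, `estimate` (`k/n`),
#'   `p_value`, `ci_low`, `ci_high`, `interval`.
#' @examples
#' exact_binomial_test(6, 24)   # p = 0.023
#' @export
exact_binomial_test <- function(k, n, p_null = 0.5,
                                interval = c("clopper-pearson", "jeffreys"),
                                conf_level = 0.95) {
  interval <- match.arg(interval)
  k <- check_count(k, "k", min = 0L)
  n <- check_count(n, "n")
  if (k > n) stop("`k` cannot exceed `n`", call. = FALSE)
  stopifnot(is.numeric(p_null), length(p_null) == 1L,
            p_null > 0, p_null < 1)
  bt <- binom.test(k, n, p = p_null, conf.level = conf_level)
  ci <- if (interval == "clopper-pearson") {
    as.numeric(bt$conf.int)
  } else {
    a <- (1 - conf_level) / 2
    c(if (k == 0L) 0 else qbeta(a, k + 0.5, n - k + 0.5),
      if (k == n) 1 else qbeta(1 - a, k + 0.5, n - k + 0.5))
  }
  structure(list(k = k, n = n, p_null = p_null, estimate = k / n,
                 p_value = as.numeric(bt$p.value),
                 ci_low = ci[1], ci_high = ci[2], interval = interval),
            class = "binomial_result")
}

#' @export
print.binomial_result <- function(x, ...) {
  cat(sprintf("Exact binomial test: %d/%d = %.3f vs %.2f\n",
              x$k, x$n, x$estimate, x$p_null))
  cat(sprintf("  two-sided P = %.4g; 95%% %s interval [%.3f, %.3f]\n",
              x$p_value, x$interval, x$ci_low, x$ci_high))
  invisible(x)
}

#' Welch's two-sample t-test
#'
#' Unequal-variance t-test with Welch-Satterthwaite degrees of freedom and a
#' two-sided p-value. When both samples are constant with equal means (no
#' variation at all), the comparison is reported as `t = 0`, `p = 1`.
#'
#' @param a,b Numeric samples, each of length at least 2.
#' @return A `two_sample_result` list: `t_stat`, `df`, `p_value`, `mean_a`,
#'   `mean_b`.
#' @examples
#' welch_t_test(rnorm(10), rnorm(12))
#' @export
welch_t_test <- function(a, b) {
  a <- as.numeric(a[!is.na(a)])
  b <- as.numeric(b[!is.na(b)])
  if (length(a) < 2L || length(b) < 2L) {
    stop("each sample needs at least two observations", call. = FALSE)
  }
  if (sd(a) == 0 && sd(b) == 0) {
    if (mean(a) == mean(b)) {
      return(structure(list(t_stat = 0, df = length(a) + length(b) - 2,
                            p_value = 1, mean_a = mean(a), mean_b = mean(b)),
                       class = "two_sample_result"))
    }
    stop("both samples are constant with different means; t is undefined",
         call. = FALSE)
  }
  tt <- t.test(a, b, var.equal = FALSE)
  structure(list(t_stat = as.numeric(tt$statistic),
                 df = as.numeric(tt$parameter),
                 p_value = as.numeric(tt$p.value),
                 mean_a = mean(a), mean_b = mean(b)),
            class = "two_sample_result")
}

#' @export
print.two_sample_result <- function(x, ...) {
  cat(sprintf("Welch two-sample t-test: t = %.5g, df = %.5g, P = %.4g\n",
              x$t_stat, x$df, x$p_value))
  cat(sprintf("  means: %.4g vs %.4g\n", x$mean_a, x$mean_b))
  invisible(x)
}

#' One-sample Wilcoxon signed-rank test
#'
#' Tests whether values are symmetric about `mu0`. Values equal to `mu0` are
#' dropped; the statistic `V` is the sum of the midranks of the positive
#' deviations. By default (`method = "normal"`) the p-value uses the normal
#' approximation with continuity correction and tie-corrected variance, and
#' a standardized effect size `r = z / sqrt(n)` is reported. With
#' `method = "exact"` (ties not allowed, `n <= 25`) the p-value is computed
#' from the exact signed-rank distribution.
#'
#' @param values Numeric vector.
#' @param mu0 Null center of symmetry.
#' @param method `"normal"` (default) or `"exact"`.
#' @return A `signed_rank_result` list: `statistic_V`, `z` (`NA` for the
#'   exact method), `p_value`, `effect_size_r` (`NA` for the exact method),
#'   `n` (non-zero deviations), `method`.
#' @examples
#' wilcoxon_one_sample(c(0.9, 0.8, 0.85, 0.95, 0.7, 0.8, 0.75), mu0 = 0.5)
#' @export
wilcoxon_one_sample <- function(values, mu0 = 0.5,
                                method = c("normal", "exact")) {
  method <- match.arg(method)
  values <- as.numeric(values[!is.na(values)])
  d <- values - mu0
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    stop("all values equal `mu0`; no non-zero deviations to rank",
         call. = FALSE)
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (method == "exact") {
    if (anyDuplicated(abs(d))) {
      stop("exact method requires untied absolute deviations", call. = FALSE)
    }
    if (n > 25L) stop("exact method is limited to n <= 25", call. = FALSE)
    p_ge <- psignrank(v - 1, n, lower.tail = FALSE)
    p_le <- psignrank(v, n)
    p <- min(1, 2 * min(p_ge, p_le))
    return(structure(list(statistic_V = v, z = NA_real_, p_value = p,
                          effect_size_r = NA_real_, n = n,
                          method = "exact"),
                     class = "signed_rank_result"))
  }
  mu_v <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  if (sigma2 <= 0) {
    stop("zero variance in the signed-rank statistic", call. = FALSE)
  }
  cc <- 0.5 * sign(v - mu_v)
  z <- (v - mu_v - cc) / sqrt(sigma2)
  if (v == mu_v) z <- 0
  p <- min(1, 2 * pnorm(-abs(z)))
  structure(list(statistic_V = v, z = z, p_value = p,
                 effect_size_r = z / sqrt(n), n = n, method = "normal"),
            class = "signed_rank_result")
}

#' @export
print.signed_rank_result <- function(x, ...) {
  cat("One-sample Wilcoxon signed-rank test (", x$method, ")\n", sep = "")
  if (x$method == "normal") {
    cat(sprintf("  V = %g, z = %.4g, P = %.4g, effect size r = %.3f\n",
                x$statistic_V, x$z, x$p_value, x$effect_size_r))
  } else {
    cat(sprintf("  V = %g, exact P = %.4g\n", x$statistic_V, x$p_value))
  }
  invisible(x)
}

#' Log-transform latencies
#'
#' Choice latencies are strongly right-skewed; location tests on them are
#' run on the natural-log scale. Non-positive or missing values are
#' rejected / propagated respectively.
#'
#' @param latency_s Numeric vector of latencies in seconds.
#' @return `log(latency_s)`.
#' @export
log_latency <- function(latency_s) {
  if (any(latency_s <= 0, na.rm = TRUE)) {
    stop("latencies must be positive to log-transform", call. = FALSE)
  }
  log(latency_s)
}
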