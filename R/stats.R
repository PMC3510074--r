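#' Bootstrap test of a synthetic mean against an observed sample
#'
#' Tests whether the mean of a simulated (synthetic) metric is compatible
#' with an observed sample of that metric. The observed sample's mean is
#' bootstrapped `n_boot` times; the synthetic mean is then compared with
#' the central `level` percentile interval of the bootstrap distribution,
#' and a two-sided probability `p = 2 min(F(m), 1 - F(m))` is reported,
#' `F` being the bootstrap CDF.
#'
#' The synthetic mean carries sampling noise of its own whenever it was
#' computed from a finite simulation. Under the null that it is the mean of
#' an independent sample of size `syn_n` from the same distribution, the
#' difference between the two means has variance `sigma^2 (1/n + 1/syn_n)`,
#' so the bootstrap distribution (variance `sigma^2 / n`) is widened by
#' `sqrt(1 + n/syn_n)` about the observed mean before comparing. The
#' default `syn_n = length(x)` matches the equal-size null and makes the
#' test reject at the nominal rate; pass `syn_n = Inf` when the synthetic
#' mean is effectively noiseless (a very long simulation), which reduces
#' to the plain percentile interval.
#'
#' @param x Observed sample (numeric, length >= 2).
#' @param syn_mean Synthetic mean to test.
#' @param n_boot Number of bootstrap resamples (>= 1000).
#' @param level Central interval coverage (default 0.95).
#' @param syn_n Sample size behind the synthetic mean (default
#'   `length(x)`; may be `Inf`).
#' @param seed Optional seed for reproducibility.
#' @return One-row tibble: `obs_mean`, `obs_sd`, `obs_n`, `syn_mean`,
#'   `ci_low`, `ci_high`, `p_value`, `inside`.
#' @export
bootstrap_mean_test <- function(x, syn_mean, n_boot = 10000, level = 0.95,
                                syn_n = length(x), seed = NULL) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 2) abort("Observed sample must have at least 2 values.")
  if (n_boot < 1000) abort("`n_boot` must be >= 1000.")
  if (level <= 0 || level >= 1) abort("`level` must be in (0, 1).")
  assert_scalar_number(syn_mean, "syn_mean")
  if (!is.null(seed)) set.seed(seed)
  m_hat <- mean(x)
  if (sd(x) == 0) {
    eq <- isTRUE(all.equal(syn_mean, m_hat))
    return(tibble(obs_mean = m_hat, obs_sd = 0, obs_n = n,
                  syn_mean = syn_mean,
                  ci_low = m_hat, ci_high = m_hat,
                  p_value = if (eq) 1 else 0, inside = eq))
  }
  scale <- sqrt(1 + n / syn_n)
  boot_means <- numeric(n_boot)
  chunk <- max(1L, min(n_boot, floor(2e6 / n)))
  done <- 0L
  while (done < n_boot) {
    k <- min(chunk, n_boot - done)
    idx <- sample.int(n, n * k, replace = TRUE)
    boot_means[done + seq_len(k)] <- colMeans(matrix(x[idx], nrow = n))
    done <- done + k
  }
  boot_means <- m_hat + scale * (boot_means - m_hat)
  alpha <- (1 - level) / 2
  ci <- unname(quantile(boot_means, c(alpha, 1 - alpha), type = 7))
  f <- mean(boot_means <= syn_mean)
  p <- min(1, 2 * min(f, 1 - f))
  tibble(obs_mean = m_hat, obs_sd = sd(x), obs_n = n, syn_mean = syn_mean,
         ci_low = ci[1], ci_high = ci[2], p_value = p,
         inside = syn_mean >= ci[1] & syn_mean <= ci[2])
}

#' Pearson correlation between real and simulated aggregate vectors
#'
#' Standard product-moment correlation with explicit guards: vectors must
#' be equally long (at least 3) and neither may be constant.
#'
#' @param real,simulated Numeric vectors, matched element-wise (e.g.
#'   per-box occupancy fractions).
#' @return Pearson r.
#' @export
occupancy_correlation <- function(real, simulated) {
  if (length(real) != length(simulated)) abort("Vectors must have equal length.")
  if (length(real) < 3) abort("At least 3 paired values are required.")
  if (sd(real) == 0 || sd(simulated) == 0) {
    abort("Correlation undefined: a vector has zero variance.")
  }
  cor(real, simulated)
}

#' Descriptive summary of a metric distribution
#'
#' Mean, median, SD, skewness and the tail ratio (mean / median), the
#' diagnostic used to justify summarising transit times by their median:
#' heavy right tails push the mean far above the median.
#'
#' @param x Non-empty numeric sample.
#' @return One-row tibble: `n`, `mean`, `median`, `sd`, `skewness`,
#'   `tail_ratio`.
#' @export
distribution_summary <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) abort("Sample is empty.")
  med <- median(x)
  tibble(n = length(x), mean = mean(x), median = med,
         sd = if (length(x) > 1) sd(x) else NA_real_,
         skewness = if (length(x) > 2) e1071::skewness(x) else NA_real_,
         tail_ratio = if (med != 0) mean(x) / med else NA_real_)
}

#' Compare observed and simulated metric sets
#'
#' Runs [bootstrap_mean_test()] for every distribution metric shared by
#' two [compute_metrics()] results: the simulated distribution is reduced
#' to its mean (with its sample size as `syn_n`) and tested against the
#' observed distribution. A normality check of the simulated distribution
#' (Shapiro-Wilk on up to 5000 values) is reported as a diagnostic column
#' only; it gates nothing.
#'
#' @param observed,simulated `metric_set` objects.
#' @param n_boot,level,seed Passed to [bootstrap_mean_test()].
#' @return A tibble of class `metric_comparison`: one row per metric with
#'   the observed mean and SD, simulated mean, interval, p-value, inside
#'   flag and the normality diagnostic.
#' @export
compare_metrics <- function(observed, simulated, n_boot = 10000,
                            level = 0.95, seed = NULL) {
  stopifnot(inherits(observed, "metric_set"), inherits(simulated, "metric_set"))
  if (!is.null(seed)) set.seed(seed)
  metrics <- intersect(unique(observed$distributions$metric),
                       unique(simulated$distributions$metric))
  rows <- lapply(metrics, function(m) {
    xo <- observed$distributions$value[observed$distributions$metric == m]
    xs <- simulated$distributions$value[simulated$distributions$metric == m]
    if (length(xo) < 2 || length(xs) < 1) return(NULL)
    res <- bootstrap_mean_test(xo, mean(xs), n_boot = n_boot, level = level,
                               syn_n = length(xs))
    res$metric <- m
    res$syn_n <- length(xs)
    res$syn_normality_p <- if (length(xs) >= 3 && sd(xs) > 0) {
      shapiro.test(if (length(xs) > 5000) sample(xs, 5000) else xs)$p.value
    } else NA_real_
    res
  })
  out <- dplyr::bind_rows(rows)
  out <- out[, c("metric", "obs_mean", "obs_sd", "obs_n", "syn_mean", "syn_n",
                 "ci_low", "ci_high", "p_value", "inside", "syn_normality_p")]
  class(out) <- c("metric_comparison", class(out))
  out
}
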