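#' Percentile bootstrap confidence interval
#'
#' Resamples the values with replacement `n_boot` times, applies the
#' statistic, and returns the (1 - level)/2 and (1 + level)/2 empirical
#' percentiles (linear interpolation between order statistics). Deterministic
#' given the seed; degenerate data give a degenerate interval.
#'
#' @param values Numeric vector (length >= 2).
#' @param statistic Function reducing a numeric vector to a scalar.
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed.
#' @return Numeric `c(low, high)`.
#' @export
#' @examples
#' bootstrap_ci(rnorm(20), mean, seed = 1)
bootstrap_ci <- function(values, statistic = mean, n_boot = 1000,
                         level = 0.95, seed = 1) {
  if (length(values) < 2) {
    stop("bootstrap needs at least 2 values", call. = FALSE)
  }
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)", call. = FALSE)
  n <- length(values)
  stats <- with_seed(seed, {
    vapply(seq_len(n_boot),
           function(i) statistic(values[sample.int(n, n, replace = TRUE)]),
           numeric(1))
  })
  unname(quantile(stats, c((1 - level) / 2, (1 + level) / 2), names = FALSE))
}

new_metric_result <- function(kind, estimate, ci, n_boot, seed, inputs,
                              units) {
  structure(list(kind = kind, estimate = estimate,
                 ci_low = ci[1], ci_high = ci[2], n_boot = n_boot,
                 seed = seed, units = units,
                 inputs_digest = ctqa_digest(inputs)),
            class = "metric_result")
}

#' @export
print.metric_result <- function(x, ...) {
  cat(sprintf("<metric_result> %s: %.4g %s  [%.4g, %.4g]  (n_boot = %d)\n",
              x$kind, x$estimate, x$units, x$ci_low, x$ci_high, x$n_boot))
  invisible(x)
}

roi_means <- function(samples) {
  stopifnot(inherits(samples, "roi_sample_set"))
  samples$samples$mean_lac
}

#' CT number accuracy (percent difference from theoretical LAC)
#'
#' 100 x (mean of the ROI means - theoretical LAC) / theoretical LAC,
#' signed; the percentile-bootstrap CI resamples the ROI means.
#'
#' @param samples A `roi_sample_set` (>= 2 samples).
#' @param theory A [material_lac()] result or a positive LAC value (cm^-1).
#' @param n_boot,seed Bootstrap settings.
#' @return A `metric_result` in percent.
#' @export
accuracy_pct <- function(samples, theory, n_boot = 1000, seed = 1) {
  th <- if (inherits(theory, "theoretical_lac")) theory$value else theory
  if (!is.numeric(th) || length(th) != 1 || th <= 0) {
    stop("theoretical LAC must be a single positive value", call. = FALSE)
  }
  m <- roi_means(samples)
  if (length(m) < 2) stop("need at least 2 samples", call. = FALSE)
  stat <- function(v) 100 * (mean(v) - th) / th
  new_metric_result("accuracy_pct", stat(m),
                    bootstrap_ci(m, stat, n_boot, seed = seed),
                    n_boot, seed, list(m, th), "%")
}

#' CT number precision (coefficient of variation of the ROI means)
#'
#' Sample SD (n-1 denominator) of the ROI means divided by their overall
#' mean; dimensionless. The bootstrap resamples the ROI means and recomputes
#' the COV on each resample.
#'
#' @inheritParams accuracy_pct
#' @return A `metric_result` (dimensionless).
#' @export
precision_cov <- function(samples, n_boot = 1000, seed = 1) {
  m <- roi_means(samples)
  if (length(m) < 2) stop("need at least 2 samples", call. = FALSE)
  if (mean(m) <= 0) {
    stop("overall mean LAC must be positive", call. = FALSE)
  }
  stat <- function(v) sd(v) / mean(v)
  new_metric_result("cov", stat(m),
                    bootstrap_ci(m, stat, n_boot, seed = seed),
                    n_boot, seed, list(m), "")
}

#' Phantom-size dependence of the measured LAC
#'
#' 100 x (L - S) / ((L + S)/2), where L and S are the means of the ROI means
#' in the large and small phantom; signed (negative when the large phantom
#' reads lower, the usual beam-hardening direction). The CI resamples the
#' two sample sets independently.
#'
#' @param samples_large,samples_small `roi_sample_set`s for the two sizes.
#' @inheritParams accuracy_pct
#' @return A `metric_result` in percent.
#' @export
size_dependence_pct <- function(samples_large, samples_small,
                                n_boot = 1000, seed = 1) {
  L <- roi_means(samples_large); S <- roi_means(samples_small)
  if (length(L) < 1 || length(S) < 1) {
    stop("both sample sets must be non-empty", call. = FALSE)
  }
  if (mean(L) + mean(S) <= 0) {
    stop("mean LAC must be positive", call. = FALSE)
  }
  est <- function(l, s) 100 * (mean(l) - mean(s)) / ((mean(l) + mean(s)) / 2)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      est(L[sample.int(length(L), replace = TRUE)],
          S[sample.int(length(S), replace = TRUE)])
    }, numeric(1))
  })
  ci <- unname(quantile(boots, c(0.025, 0.975), names = FALSE))
  new_metric_result("size_dependence_pct", est(L, S), ci, n_boot, seed,
                    list(L, S), "%")
}

#' Background noise (mean within-ROI SD)
#'
#' Mean of the within-ROI standard deviations, in cm^-1, computed on the
#' background insert (blood, i.e. 0 mg/mL iodine). The CI resamples the
#' per-sample SDs.
#'
#' @inheritParams accuracy_pct
#' @return A `metric_result` in cm^-1.
#' @export
background_sd <- function(samples, n_boot = 1000, seed = 1) {
  s <- samples$samples$sd_lac
  if (length(s) < 1) stop("need at least 1 sample", call. = FALSE)
  ci <- if (length(s) >= 2) bootstrap_ci(s, mean, n_boot, seed = seed)
        else c(mean(s), mean(s))
  new_metric_result("background_sd", mean(s), ci, n_boot, seed, list(s),
                    "cm^-1")
}
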