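fixed_set <- function(means, sds = rep(0, length(means))) {
  structure(list(insert_id = "x",
                 samples = data.frame(slice = seq_along(means),
                                      repeat_index = 1, mean_lac = means,
                                      sd_lac = sds),
                 lac_water_ref = NA_real_, n_roi_voxels = 29),
            class = "roi_sample_set")
}

test_that("accuracy is the signed percent difference from theory", {
  th <- 0.25
  expect_equal(accuracy_pct(fixed_set(rep(th, 20)), th)$estimate, 0)
  r <- accuracy_pct(fixed_set(rep(1.02 * th, 20)), th)
  expect_equal(r$estimate, 2.0, tolerance = 1e-12)
  expect_equal(c(r$ci_low, r$ci_high), c(2, 2), tolerance = 1e-12)
  # scale invariance: multiplying all LAC by k leaves the estimate unchanged
  m <- 0.25 * (1 + rnorm(20, 0, 0.01))
  a1 <- accuracy_pct(fixed_set(m), 0.25)$estimate
  a2 <- accuracy_pct(fixed_set(7 * m), 7 * 0.25)$estimate
  expect_equal(a1, a2, tolerance = 1e-12)
  expect_error(accuracy_pct(fixed_set(m), -1), "positive")
  expect_error(accuracy_pct(fixed_set(0.25), 0.25), "2 samples")
})

test_that("COV matches two-point arithmetic and is scale invariant", {
  r <- precision_cov(fixed_set(c(0.9, 1.1)))
  expect_equal(r$estimate, sqrt(0.02) / 1.0, tolerance = 1e-12)
  m <- abs(rnorm(20, 1, 0.05))
  expect_equal(precision_cov(fixed_set(m))$estimate,
               precision_cov(fixed_set(3 * m))$estimate, tolerance = 1e-12)
  expect_equal(precision_cov(fixed_set(rep(0.2, 20)))$estimate, 0)
  expect_error(precision_cov(fixed_set(c(-1, -2))), "positive")
})

test_that("size dependence uses the symmetrized denominator and antisymmetry", {
  L <- fixed_set(rep(1.05, 20)); S <- fixed_set(rep(0.95, 20))
  r <- size_dependence_pct(L, S)
  expect_equal(r$estimate, 10.0, tolerance = 1e-12)
  expect_equal(size_dependence_pct(S, L)$estimate, -r$estimate,
               tolerance = 1e-12)
  expect_equal(size_dependence_pct(L, L)$estimate, 0)
  # closed form for a +2%/0% size-dependent bias
  th <- 0.3
  r2 <- size_dependence_pct(fixed_set(rep(1.02 * th, 20)),
                            fixed_set(rep(th, 20)))
  expect_equal(r2$estimate, 100 * 0.02 / 1.01, tolerance = 1e-12)
})

test_that("background noise metric averages the within-ROI SDs", {
  s <- fixed_set(rep(0.2, 20), sds = rep(0.004, 20))
  r <- background_sd(s)
  expect_equal(r$estimate, 0.004)
  expect_equal(c(r$ci_low, r$ci_high), c(0.004, 0.004))
  expect_equal(background_sd(fixed_set(rep(0.2, 20)))$estimate, 0)
})

test_that("bootstrap CI is deterministic, degenerate-safe, and ordered", {
  x <- rnorm(20)
  ci1 <- bootstrap_ci(x, mean, seed = 7)
  ci2 <- bootstrap_ci(x, mean, seed = 7)
  expect_identical(ci1, ci2)
  expect_false(identical(ci1, bootstrap_ci(x, mean, seed = 8)))
  expect_lte(ci1[1], ci1[2])
  expect_identical(bootstrap_ci(rep(1.5, 10), mean, seed = 1), c(1.5, 1.5))
  expect_error(bootstrap_ci(1, mean), "at least 2")
  expect_error(bootstrap_ci(1:5, mean, level = 1.2), "level")
  # CI brackets the point estimate for the mean statistic
  expect_lte(ci1[1], mean(x)); expect_gte(ci1[2], mean(x))
})

test_that("metric results are reproducible and carry provenance", {
  m <- rnorm(20, 0.25, 0.002)
  r1 <- accuracy_pct(fixed_set(m), 0.25, seed = 3)
  r2 <- accuracy_pct(fixed_set(m), 0.25, seed = 3)
  expect_identical(r1$inputs_digest, r2$inputs_digest)
  expect_identical(c(r1$ci_low, r1$ci_high), c(r2$ci_low, r2$ci_high))
  expect_true(r1$ci_low <= r1$estimate && r1$estimate <= r1$ci_high)
})

test_that("estimators recover injected truth in a small simulation", {
  # scaled-down recovery check; the full 500-replicate version runs in the
  # acceptance suite
  hits <- 0
  for (i in 1:50) {
    s <- statistical_roi_generator(0.25, bias_pct = 3, noise_sd = 0.002,
                                   seed = i)
    r <- accuracy_pct(s, 0.25, seed = i)
    if (r$ci_low <= 3 && 3 <= r$ci_high) hits <- hits + 1
  }
  expect_gte(hits, 40)
})
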