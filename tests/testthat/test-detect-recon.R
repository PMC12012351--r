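test_that("detection reproduces the air scan and Beer-Lambert exactly", {
  g <- tiny_geom()
  ph <- build_phantom("small", list())
  paths <- forward_project(ph, g)
  # monoenergetic delta spectrum: p = mu_w(70) * t exactly (Beer-Lambert)
  acq <- delta_acq(70)
  sino <- detect(paths, acq)
  muw <- lac_value(ctqa_material("water"), 70)
  t_cm <- matrix(paths$lengths_mm[, 1] / 10, g$n_det, g$n_views)
  expect_equal(sino$channels[[1]], muw * t_cm, tolerance = 1e-12)
  # rays missing the object detect the air-scan signal: p = 0
  expect_true(all(sino$channels[[1]][abs(g$s) > 90, ] == 0))
})

test_that("polyenergetic effective attenuation falls with thickness", {
  acq <- acquisition_model("SECT")
  ch <- ctqa:::acq_channels(acq)[[1]]
  muw <- lac_value(ctqa_material("water"), ch$energies)
  t_cm <- c(2, 5, 10, 20, 30, 40)
  p <- vapply(t_cm, function(t) {
    -log(sum(ch$w * exp(-muw * t)) / sum(ch$w))
  }, numeric(1))
  expect_true(all(diff(p / t_cm) < 0))  # beam hardening
})

test_that("water beam-hardening correction is self-consistent", {
  acq <- acquisition_model("SECT")
  cal <- water_bhc_calibrate(acq)
  # corrected integral for a pure-water ray of thickness t: mu_ref * t
  ch <- ctqa:::acq_channels(acq)[[1]]
  muw <- lac_value(ctqa_material("water"), ch$energies)
  for (t_mm in c(0, 47, 180, 333)) {
    p <- -log(sum(ch$w * exp(-muw * t_mm / 10)) / sum(ch$w))
    expect_equal(apply_bhc(p, cal), cal$mu_ref * t_mm / 10, tolerance = 1e-9)
  }
  expect_equal(apply_bhc(0, cal), 0)
})

test_that("FBP is linear and recovers a uniform disk within 1%", {
  g <- ct_geometry(720, 367, 1)
  zero <- matrix(0, g$n_det, g$n_views)
  expect_equal(fbp_reconstruct(zero, g), matrix(0, 256, 256))
  # uniform disk mu = 0.2 cm^-1, r = 80 mm, monoenergetic line integrals
  r <- 80
  chord_cm <- 2 * sqrt(pmax(r^2 - g$s^2, 0)) / 10
  sino <- matrix(0.2 * chord_cm, g$n_det, g$n_views)
  img <- fbp_reconstruct(sino, g)
  mask <- roi_mask(3)
  ctr <- img[cbind(128 + mask[, "dr"], 128 + mask[, "dc"])]
  expect_equal(mean(ctr), 0.2, tolerance = 0.01)
  # linearity: doubling the sinogram doubles the image exactly
  expect_equal(fbp_reconstruct(2 * sino, g), 2 * img, tolerance = 1e-12)
  g_few <- ct_geometry(100, 345, 1)
  expect_warning(fbp_reconstruct(matrix(0, 345, 100), g_few), "aliasing")
})

test_that("a water-only disk reconstructs flat after the water correction", {
  g <- ct_geometry(720, 367, 1)
  ph <- build_phantom("small", list())
  paths <- forward_project(ph, g)
  acq <- acquisition_model("SECT")
  sino <- detect(paths, acq)
  cal <- water_bhc_calibrate(acq)
  img <- fbp_reconstruct(apply_bhc(sino$channels[[1]], cal), g)
  mask <- roi_mask(3)
  sample_at <- function(r0, c0) {
    mean(img[cbind(r0 + mask[, "dr"], c0 + mask[, "dc"])])
  }
  center <- sample_at(128, 128)
  # near-edge ROI, 70 mm off-center (insert ring territory and beyond)
  edge <- sample_at(128, 128 + round(70 / (360 / 256)))
  expect_equal(center, cal$mu_ref, tolerance = 0.005)
  expect_lt(abs(edge - center) / center, 0.005)
})

test_that("noisy detection is seed-deterministic and unbiased at high fluence", {
  g <- ct_geometry(60, 345, 1)
  paths <- forward_project(build_phantom("small", list()), g)
  acq <- acquisition_model("PCCT", fluence_per_ray = 1e6)
  expd <- detect_expected(paths, acq)
  s1 <- detect_sample(expd, 1e6, seed = 42)
  s2 <- detect_sample(expd, 1e6, seed = 42)
  expect_identical(s1$channels, s2$channels)
  s3 <- detect_sample(expd, 1e6, seed = 43)
  expect_false(identical(s1$channels[[1]], s3$channels[[1]]))
  # noisy p fluctuates around the noise-free p
  p0 <- detect_sample(expd, Inf)$channels[[1]]
  expect_lt(abs(mean(s1$channels[[1]] - p0)), 1e-3)
  expect_error(detect_sample(expd, 1e6), "seed")
})
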