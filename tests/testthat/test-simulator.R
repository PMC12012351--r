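# scaled-down geometry keeps these structural checks fast; the full-scale
# physics checks run in the acceptance suite
small_cfg <- function(...) {
  simulate_config(n_views = 180, n_det = 345, n_pix = 128,
                  pixel_mm = 360 / 128, ...)
}

test_that("study output counts follow modalities x sizes x repeats", {
  cfg <- small_cfg(sizes = c("small", "large"), series = "calcium",
                   n_repeats = 5, n_slices = 1, fluence_per_ray = Inf)
  stacks <- simulate_study(cfg, master_seed = 1)
  expect_length(stacks, 3 * 2 * 5)
  expect_setequal(unique(vapply(stacks, `[[`, character(1), "modality")),
                  c("SECT", "DECT", "PCCT"))
  # SECT stacks carry no VMI energy; spectral stacks carry 70 keV
  for (st in stacks) {
    if (st$modality == "SECT") expect_true(is.na(st$vmi_energy))
    else expect_equal(st$vmi_energy, 70)
  }
})

test_that("the same master seed reproduces the study bit for bit", {
  cfg <- small_cfg(modalities = c("SECT", "PCCT"), sizes = "small",
                   series = "iodine", n_repeats = 2, n_slices = 2,
                   fluence_per_ray = 1e6)
  s1 <- simulate_study(cfg, master_seed = 9)
  s2 <- simulate_study(cfg, master_seed = 9)
  for (i in seq_along(s1)) expect_identical(s1[[i]]$voxels, s2[[i]]$voxels)
  s3 <- simulate_study(cfg, master_seed = 10)
  expect_false(identical(s1[[1]]$voxels, s3[[1]]$voxels))
})

test_that("repeats differ only by their noise realization", {
  cfg <- small_cfg(modalities = "SECT", sizes = "small", series = "calcium",
                   n_repeats = 2, n_slices = 1, fluence_per_ray = 1e6)
  stacks <- simulate_study(cfg, master_seed = 3)
  d <- stacks[[1]]$voxels - stacks[[2]]$voxels
  expect_gt(sd(d), 0)                  # distinct realizations
  expect_lt(abs(mean(d)), 1)           # same underlying image (HU)
  # noise-free repeats are identical
  cfg0 <- small_cfg(modalities = "SECT", sizes = "small", series = "calcium",
                    n_repeats = 2, n_slices = 1, fluence_per_ray = Inf)
  st0 <- simulate_study(cfg0, master_seed = 3)
  expect_identical(st0[[1]]$voxels, st0[[2]]$voxels)
})

test_that("air outside the body reads near -1000 HU and water near 0 HU", {
  cfg <- small_cfg(modalities = "SECT", sizes = "small", series = "calcium",
                   n_repeats = 1, n_slices = 1, fluence_per_ray = Inf)
  st <- simulate_study(cfg, master_seed = 1)[[1]]
  img <- st$voxels[1, , ]
  n <- dim(img)[1]
  expect_lt(abs(img[n %/% 2, n %/% 2]), 15)         # water center, HU
  # air above the phantom; the coarse 128-px test grid leaves a larger
  # truncation artifact near the FOV edge than the default 256-px grid
  expect_lt(abs(img[4, n %/% 2] + 1000), 120)
})

test_that("config validation reports field paths", {
  expect_error(simulate_config(modalities = "MRI"), "config\\$modalities")
  expect_error(simulate_config(sizes = "tiny"), "config\\$sizes")
  expect_error(simulate_config(vmi_energies = 20), "config\\$vmi_energies")
  expect_error(simulate_config(fluence_per_ray = 0), "config\\$fluence")
  expect_error(simulate_config(n_det = 100), "config\\$n_det")
})

test_that("ROI extraction from simulated stacks recovers insert LAC", {
  cfg <- small_cfg(modalities = "PCCT", sizes = "small", series = "iodine",
                   n_repeats = 1, n_slices = 1, fluence_per_ray = Inf)
  stacks <- simulate_study(cfg, master_seed = 1)
  sets <- sample_study_rois(stacks)[[1]]
  mats <- insert_series("iodine")
  for (nm in names(sets)) {
    th <- lac_value(mats[[nm]], 70)
    expect_equal(mean(sets[[nm]]$samples$mean_lac), th, tolerance = 0.02)
    expect_lt(sets[[nm]]$samples$sd_lac[1] / th, 0.02)  # noise-free
  }
})
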