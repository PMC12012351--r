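test_that("HU to LAC conversion has the printed fixed points and is invertible", {
  expect_identical(hu_to_lac(0, 0.1929), 0.1929)
  expect_identical(hu_to_lac(-1000, 0.1929), 0)
  expect_equal(hu_to_lac(1000, 0.1929), 0.3858, tolerance = 1e-12)
  hu <- seq(-1000, 3000, by = 37)
  expect_equal(lac_to_hu(hu_to_lac(hu, 0.1929), 0.1929), hu, tolerance = 1e-12)
  expect_error(hu_to_lac(0, 0), "lac_water")
  expect_error(lac_to_hu(0.1, -1), "lac_water")
})

test_that("ROI masks follow the center-distance rule", {
  m1 <- roi_mask(1)
  expect_equal(nrow(m1), 5)  # plus-shape
  m3 <- roi_mask(3)
  # brute-force enumeration oracle
  brute <- sum(outer(-3:3, -3:3, function(a, b) a^2 + b^2) <= 9)
  expect_equal(nrow(m3), brute)
  expect_equal(nrow(m3), 29)
  # 4-fold symmetry under row/col reflection
  key <- function(m) sort(paste(m[, 1], m[, 2]))
  expect_identical(key(m3), key(cbind(-m3[, 1], m3[, 2])))
  expect_identical(key(m3), key(cbind(m3[, 1], -m3[, 2])))
  expect_error(roi_mask(0), "radius")
})

test_that("uniform stacks give 20 exact samples with zero SD", {
  stacks <- lapply(1:5, function(r) constant_stack(100, repeat_index = r))
  sets <- sample_rois(stacks, specs = list(a = center_spec()),
                      lac_water_ref = 0.2)
  s <- sets$a$samples
  expect_equal(nrow(s), 20)  # 4 slices x 5 repeats
  expect_equal(s$mean_lac, rep(hu_to_lac(100, 0.2), 20))
  expect_equal(s$sd_lac, rep(0, 20))
})

test_that("checkerboard ROI statistics match direct enumeration", {
  n <- 64
  vox <- array(0, c(1, n, n))
  vox[1, , ] <- outer(1:n, 1:n, function(r, c) ifelse((r + c) %% 2 == 0,
                                                      200, -100))
  st <- constant_stack(voxels = vox, n_slices = 1)
  sets <- sample_rois(list(st), specs = list(a = center_spec(n)),
                      lac_water_ref = 0.2)
  # direct enumeration over the same mask
  mask <- roi_mask(3)
  ctr <- n %/% 2
  vals <- vox[1, , ][cbind(ctr + mask[, "dr"] + 1, ctr + mask[, "dc"] + 1)]
  expect_equal(sets$a$samples$mean_lac, hu_to_lac(mean(vals), 0.2))
  expect_equal(sets$a$samples$sd_lac, sd(hu_to_lac(vals, 0.2)))
})

test_that("ROI statistics are invariant to stack order and bounds are checked", {
  stacks <- lapply(1:5, function(r) {
    st <- constant_stack(0, repeat_index = r)
    st$voxels <- st$voxels + r  # distinguishable repeats
    st
  })
  spec <- list(a = center_spec())
  fwd <- sample_rois(stacks, spec, 0.2)$a$samples
  rev <- sample_rois(stacks[5:1], spec, 0.2)$a$samples
  ord <- function(d) d[order(d$repeat_index, d$slice), ]
  expect_equal(ord(fwd), ord(rev), ignore_attr = TRUE)
  expect_error(sample_rois(stacks, list(a = roi_spec("a", c(1, 1), 3)), 0.2),
               "outside the image")
})

test_that("image stacks round-trip through NIfTI + sidecar", {
  dir <- withr::local_tempdir()
  st <- constant_stack(0)
  st$voxels[] <- round(rnorm(length(st$voxels), 0, 50), 3)
  st$phantom <- list(size_label = "small", body_diameter = 180,
                     insert_id = "a", insert_x = 0, insert_y = 0,
                     insert_radius = 15, insert_material = "water")
  write_image_stacks(list(st), dir)
  back <- load_image_stacks(dir)
  expect_length(back, 1)
  expect_equal(back[[1]]$voxels, st$voxels, tolerance = 1e-6)
  expect_equal(back[[1]]$modality, st$modality)
  expect_equal(back[[1]]$vmi_energy, st$vmi_energy)
  expect_equal(back[[1]]$lac_water_ref, st$lac_water_ref)
})

test_that("sidecar rescale slope/intercept is applied on load", {
  dir <- withr::local_tempdir()
  st <- constant_stack(1024, n_slices = 1, n_pix = 16)
  stem <- write_image_stacks(list(st), dir)
  side <- file.path(dir, paste0(stem, ".json"))
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  meta$rescale_slope <- 1
  meta$rescale_intercept <- -1024
  jsonlite::write_json(meta, side, auto_unbox = TRUE, digits = NA,
                       null = "null")
  back <- load_image_stacks(dir)
  expect_equal(unique(as.vector(back[[1]]$voxels)), 0)
  # a missing sidecar is a format error
  file.remove(side)
  expect_error(load_image_stacks(dir), "sidecar")
})
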