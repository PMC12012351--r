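# forward-model helper: exact two-channel log signals for known basis
# line integrals (t1 cm of water, t2 g/cm^2 of solute)
two_channel_signals <- function(acq, basis_element, t1, t2) {
  chans <- ctqa:::acq_channels(acq)
  lapply(chans, function(ch) {
    bf <- ctqa:::basis_functions(ch$energies, basis_element)
    wn <- ch$w / sum(ch$w)
    p <- vapply(seq_along(t1), function(i) {
      -log(sum(wn * exp(-bf$f1 * t1[i] - bf$f2 * t2[i])))
    }, numeric(1))
    matrix(p, length(t1), 1)
  })
}

fake_sinoset <- function(acq, channels) {
  n <- nrow(channels[[1]])
  g <- structure(list(n_views = 1L, n_det = n, det_pitch_mm = 1,
                      theta = 0, s = seq_len(n) - (n + 1) / 2),
                 class = "ct_geometry")
  structure(list(channels = channels, geometry = g, acq = acq,
                 fluence = Inf, seed = NULL), class = "ct_sinogram_set")
}

test_that("projection decomposition round-trips known basis integrals", {
  acq <- acquisition_model("PCCT")
  t1 <- c(0, 5, 10, 20, 30, 33)          # cm water
  t2 <- c(0, 0, 0.5, 1.5, 3, 7.9)        # g/cm^2 calcium
  sig <- two_channel_signals(acq, "Ca", t1, t2)
  td <- basis_decompose_projection(fake_sinoset(acq, sig), "Ca")
  # 1e-6 mm = 1e-7 cm on the water thickness
  expect_equal(as.vector(td$t1), t1, tolerance = 1e-7)
  expect_equal(as.vector(td$t2), t2, tolerance = 1e-7)
})

test_that("water-only rays decompose to (t, 0)", {
  acq <- acquisition_model("DECT")
  t1 <- c(2, 15, 33)
  sig <- two_channel_signals(acq, "I", t1, rep(0, 3))
  td <- basis_decompose_projection(fake_sinoset(acq, sig), "I")
  expect_equal(as.vector(td$t1), t1, tolerance = 1e-7)
  expect_equal(as.vector(td$t2), rep(0, 3), tolerance = 1e-7)
})

test_that("spectrally identical channels are rejected as singular", {
  acq <- acquisition_model("DECT", kvp = c(140, 140))
  sig <- two_channel_signals(acq, "I", c(10, 20), c(0, 0))
  expect_error(basis_decompose_projection(fake_sinoset(acq, sig), "I"),
               "identical|singular")
})

test_that("VMI synthesis reproduces water and supports all study energies", {
  muw70 <- lac_value(ctqa_material("water"), 70)
  a_w <- matrix(1, 4, 4); a_b <- matrix(0, 4, 4)
  for (E in c(40, 60, 70, 90, 110, 130)) {
    vmi <- synthesize_vmi(a_w, a_b, E, "I")
    expect_equal(vmi, matrix(lac_value(ctqa_material("water"), E), 4, 4))
  }
  # image-domain solve is the exact inverse of synthesis at the two energies
  dec <- basis_decompose_image(
    img1 = 0.7 * lac_value(ctqa_material("water"), 76) +
      0.01 * element_mac(element_table("I"), 76),
    img2 = 0.7 * lac_value(ctqa_material("water"), 53) +
      0.01 * element_mac(element_table("I"), 53),
    energy1 = 76, energy2 = 53, basis_element = "I")
  expect_equal(dec$a_w, 0.7, tolerance = 1e-10)
  expect_equal(dec$a_b, 0.01, tolerance = 1e-10)
})

test_that("VMI at the channel effective energies reproduces the channel images", {
  acq <- acquisition_model("PCCT")
  chans <- ctqa:::acq_channels(acq)
  # thin paths: the small-thickness limit of a finite-width bin is the
  # fluence-weighted mean of the basis functions over the bin (not their
  # value at the mean energy); thick paths are covered by the exact
  # round-trip check above
  t1 <- c(0.3, 1); t2 <- c(0.005, 0.02)
  sig <- two_channel_signals(acq, "Ca", t1, t2)
  td <- basis_decompose_projection(fake_sinoset(acq, sig), "Ca")
  for (k in 1:2) {
    ch <- chans[[k]]
    bf <- ctqa:::basis_functions(ch$energies, "Ca")
    f1_eff <- sum(ch$w * bf$f1) / sum(ch$w)
    f2_eff <- sum(ch$w * bf$f2) / sum(ch$w)
    p_eff <- f1_eff * td$t1 + f2_eff * td$t2
    expect_equal(as.vector(p_eff), as.vector(sig[[k]]), tolerance = 0.02)
  }
})
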