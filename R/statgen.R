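#' Statistical-tier ROI sample generator
#'
#' Emits per-insert ROI sample sets directly from a declared bias/noise
#' model, bypassing the physics simulation: ROI means are drawn as
#' theory x (1 + bias/100) + Gaussian(0, noise_sd / sqrt(n_roi_voxels)),
#' and within-ROI SDs as noise_sd x sqrt(chi^2_(n-1) / (n-1)), consistent
#' with Gaussian voxel noise of standard deviation `noise_sd` averaged over
#' an ROI of `n_roi_voxels` voxels. This fast tier drives estimator
#' validation and the full VMI energy sweep.
#'
#' @param theory_lac Theoretical LAC of the insert, cm^-1.
#' @param bias_pct Injected relative bias in percent (signed).
#' @param noise_sd Voxel-level noise SD in cm^-1 (>= 0).
#' @param n_slices,n_repeats Sample layout (defaults 4 x 5 = 20 samples).
#' @param n_roi_voxels Voxels per ROI (default 29, a radius-3 ROI).
#' @param seed Integer seed.
#' @param insert_id Label for the generated set.
#' @return A `roi_sample_set` with `n_slices * n_repeats` rows.
#' @export
#' @examples
#' s <- statistical_roi_generator(0.25, bias_pct = 3, noise_sd = 0.004,
#'                                seed = 1)
#' nrow(s$samples)  # 20
statistical_roi_generator <- function(theory_lac, bias_pct = 0,
                                      noise_sd = 0, n_slices = 4,
                                      n_repeats = 5, n_roi_voxels = 29,
                                      seed = 1, insert_id = "insert") {
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  n <- n_slices * n_repeats
  draw <- function() {
    mu <- theory_lac * (1 + bias_pct / 100) +
      rnorm(n, 0, noise_sd / sqrt(n_roi_voxels))
    sds <- if (noise_sd > 0) {
      noise_sd * sqrt(rchisq(n, df = n_roi_voxels - 1) / (n_roi_voxels - 1))
    } else rep(0, n)
    list(mu = mu, sds = sds)
  }
  d <- with_seed(seed, draw())
  grid <- expand.grid(slice = seq_len(n_slices),
                      repeat_index = seq_len(n_repeats))
  structure(list(insert_id = insert_id,
                 samples = data.frame(slice = grid$slice,
                                      repeat_index = grid$repeat_index,
                                      mean_lac = d$mu, sd_lac = d$sds),
                 lac_water_ref = NA_real_, n_roi_voxels = n_roi_voxels),
            class = "roi_sample_set")
}

#' Declared bias/noise model for the statistical tier
#'
#' A stylized parametric stand-in for the physics tier across the VMI energy
#' sweep. The relative bias is proportional to the insert's excess
#' attenuation over water at the evaluation energy (the driver of residual
#' beam hardening), scaled by a path-length factor per phantom size and a
#' modality coefficient ordered SECT >> DECT >> PCCT; the sign is negative
#' (hardening depresses measured attenuation, more so in the large phantom).
#' Voxel noise grows with phantom size, is ~30% lower for the
#' photon-counting style, and increases toward low VMI energies.
#'
#' @param material A [ct_material()] insert.
#' @param modality `"SECT"`, `"DECT"`, or `"PCCT"`.
#' @param size `"small"` or `"large"`.
#' @param energy Evaluation energy in keV.
#' @param water Water reference material.
#' @return List with `bias_pct` and `noise_sd` (cm^-1).
#' @export
default_bias_model <- function(material, modality, size, energy,
                               water = ctqa_material("water")) {
  beta <- c(SECT = 3.3, DECT = 0.6, PCCT = 0.04)[[modality]]
  path <- c(small = 1, large = 2.5)[[size]]
  excess <- lac_value(material, energy) / lac_value(water, energy) - 1
  sigma0 <- 0.004                                  # cm^-1, ~20 HU at 70 keV
  g_size <- c(small = 1, large = 2)[[size]]
  h_mod <- c(SECT = 1, DECT = 1, PCCT = 0.7)[[modality]]
  w_energy <- 0.5 + 35 / energy                    # noise rises at low keV
  list(bias_pct = -beta * path * excess,
       noise_sd = sigma0 * g_size * h_mod * w_energy)
}
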