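#' Default simulation configuration
#'
#' Desk-scale defaults reproducing the study's design dimensions: three
#' acquisition styles, two phantom sizes, both insert series, 4 central
#' slices x 5 repeats, 256^2 grid, 720 views, 367 detectors at 1 mm pitch.
#' Slices of the (axially uniform) digital phantom differ only by their
#' noise realization. The default fluence of 1e7 photons/ray is a dose
#' proxy yielding background noise of roughly 5 HU (small phantom) to 10 HU
#' (large phantom) in the reconstructed images, the regime of a quality-
#' assurance protocol where deterministic bias dominates quantum noise.
#'
#' @param modalities Subset of `c("SECT", "DECT", "PCCT")`.
#' @param sizes Subset of `c("small", "large")`.
#' @param series Subset of `c("iodine", "calcium")`.
#' @param vmi_energies VMI energies in keV for DECT/PCCT (default 70; the
#'   full 40-130 keV sweep is handled by the statistical tier).
#' @param n_slices,n_repeats Central slices and repeat scans (defaults 4, 5).
#' @param fluence_per_ray Photons per ray in air; `Inf` turns noise off.
#' @param n_views,n_det,det_pitch_mm Acquisition geometry.
#' @param n_pix,pixel_mm Reconstruction grid (default 256 px, 360 mm FOV).
#' @param bin_width Spectrum bin width in keV.
#' @return A validated `simulate_config` list.
#' @export
simulate_config <- function(modalities = c("SECT", "DECT", "PCCT"),
                            sizes = c("small", "large"),
                            series = c("iodine", "calcium"),
                            vmi_energies = 70,
                            n_slices = 4, n_repeats = 5,
                            fluence_per_ray = 1e7,
                            n_views = 720, n_det = 367, det_pitch_mm = 1,
                            n_pix = 256, pixel_mm = 360 / 256,
                            bin_width = 2) {
  cfg <- list(modalities = modalities, sizes = sizes, series = series,
              vmi_energies = vmi_energies, n_slices = n_slices,
              n_repeats = n_repeats, fluence_per_ray = fluence_per_ray,
              n_views = n_views, n_det = n_det, det_pitch_mm = det_pitch_mm,
              n_pix = n_pix, pixel_mm = pixel_mm, bin_width = bin_width)
  validate_simulate_config(cfg)
  structure(cfg, class = "simulate_config")
}

validate_simulate_config <- function(cfg) {
  chk <- function(ok, field, msg) {
    if (!ok) stop(sprintf("config$%s: %s", field, msg), call. = FALSE)
  }
  chk(all(cfg$modalities %in% c("SECT", "DECT", "PCCT")), "modalities",
      "must be among SECT, DECT, PCCT")
  chk(length(cfg$modalities) >= 1, "modalities", "must be non-empty")
  chk(all(cfg$sizes %in% c("small", "large")), "sizes",
      "must be among small, large")
  chk(all(cfg$series %in% c("iodine", "calcium")), "series",
      "must be among iodine, calcium")
  chk(all(cfg$vmi_energies >= 40 & cfg$vmi_energies <= 130), "vmi_energies",
      "must lie in [40, 130] keV")
  chk(cfg$n_slices >= 1, "n_slices", "must be >= 1")
  chk(cfg$n_repeats >= 1, "n_repeats", "must be >= 1")
  chk(cfg$fluence_per_ray > 0, "fluence_per_ray", "must be > 0")
  chk(cfg$n_det * cfg$det_pitch_mm >= 340, "n_det",
      "detector span must cover the 330 mm phantom")
  invisible(cfg)
}

# one reconstructed slice per requested image channel, as HU matrices.
# Returns a named list: "SECT" or "E<keV>" -> list(hu, lac_water_ref, energy)
reconstruct_slice <- function(sino, modality, pre, cfg, water) {
  g <- sino$geometry
  if (modality == "SECT") {
    corr <- apply_bhc(sino$channels[[1]], pre$cal)
    img <- fbp_reconstruct(corr, g, cfg$n_pix, cfg$pixel_mm)
    hu <- 1000 * (img / pre$cal$mu_ref - 1)
    return(list(SECT = list(hu = hu, lac_water_ref = pre$cal$mu_ref,
                            energy = pre$cal$mean_energy)))
  }
  if (modality == "DECT") {
    imgs <- lapply(1:2, function(k) {
      corr <- apply_bhc(sino$channels[[k]], pre$cals[[k]]) + pre$dq[[k]]
      fbp_reconstruct(corr, g, cfg$n_pix, cfg$pixel_mm)
    })
    dec <- basis_decompose_image(imgs[[1]], imgs[[2]],
                                 pre$cals[[1]]$mean_energy,
                                 pre$cals[[2]]$mean_energy,
                                 pre$basis_element, water)
  } else {  # PCCT: projection-domain decomposition
    td <- basis_decompose_projection(sino, pre$basis_element, water,
                                     t_start = pre$t_start)
    dec <- list(a_w = fbp_reconstruct(td$t1, g, cfg$n_pix, cfg$pixel_mm),
                a_b = fbp_reconstruct(td$t2, g, cfg$n_pix, cfg$pixel_mm))
  }
  out <- lapply(cfg$vmi_energies, function(E) {
    mu <- synthesize_vmi(dec$a_w, dec$a_b, E, pre$basis_element, water)
    muw <- lac_value(water, E)
    list(hu = 1000 * (mu / muw - 1), lac_water_ref = muw, energy = E)
  })
  names(out) <- paste0("E", cfg$vmi_energies)
  out
}

#' Simulate the full phantom study
#'
#' For every series x phantom size x modality, forward-projects the phantom
#' analytically, detects polyenergetic signals, adds quantum noise per
#' (repeat, slice) with seeds derived from the master seed, reconstructs,
#' decomposes (DECT in the image domain, PCCT in the projection domain), and
#' converts to HU using the water LAC at the VMI energy (for SECT, at the
#' spectrum mean energy). The output is one [image stack][sample_rois] per
#' (series, modality, size, repeat, VMI energy); repeats differ only by
#' their noise realization, and the same master seed reproduces the output
#' bit for bit.
#'
#' @param config A [simulate_config()].
#' @param master_seed Integer master seed for all noise streams.
#' @return A list of `image_stack` objects (class `image_stack_set`).
#' @export
#' @examples
#' \donttest{
#' cfg <- simulate_config(modalities = "PCCT", sizes = "small",
#'                        series = "calcium", n_repeats = 1, n_slices = 1,
#'                        fluence_per_ray = Inf, n_views = 180, n_det = 345,
#'                        n_pix = 128, pixel_mm = 360 / 128)
#' stacks <- simulate_study(cfg, master_seed = 1)
#' }
simulate_study <- function(config = simulate_config(), master_seed = 1) {
  validate_simulate_config(config)
  water <- ctqa_material("water")
  geom <- ct_geometry(config$n_views, config$n_det, config$det_pitch_mm)
  noise_on <- is.finite(config$fluence_per_ray)
  stacks <- list()
  for (series_name in config$series) {
    mats <- insert_series(series_name)
    basis_el <- attr(mats, "solute")
    for (size in config$sizes) {
      ph <- build_phantom(size, mats, n_slices = config$n_slices)
      paths <- forward_project(ph, geom)
      for (mod in config$modalities) {
        acq <- acquisition_model(mod, fluence_per_ray = config$fluence_per_ray,
                                 bin_width = config$bin_width)
        expd <- detect_expected(paths, acq)
        chans <- acq_channels(acq)
        pre <- list(basis_element = basis_el)
        if (mod == "SECT") {
          pre$cal <- water_bhc_calibrate(chans[[1]], water)
        } else if (mod == "DECT") {
          pre$cals <- lapply(chans, water_bhc_calibrate, water = water)
          sino0 <- detect_sample(expd, Inf)
          pre$dq <- dect_second_pass(sino0, pre$cals, basis_el,
                                     config$n_pix, config$pixel_mm, water)
        } else {
          # noise-free solve warm-starts every noisy realization
          sino0 <- detect_sample(expd, Inf)
          pre$t_start <- basis_decompose_projection(sino0, basis_el, water)
        }
        for (rep_i in seq_len(config$n_repeats)) {
          slices <- vector("list", config$n_slices)
          for (sl in seq_len(config$n_slices)) {
            sd_i <- child_seed(master_seed, series_name, size, mod, rep_i, sl)
            sino <- if (noise_on) detect_sample(expd, config$fluence_per_ray,
                                                sd_i)
                    else detect_sample(expd, Inf)
            slices[[sl]] <- reconstruct_slice(sino, mod, pre, config, water)
          }
          for (chan_name in names(slices[[1]])) {
            vox <- array(0, c(config$n_slices, config$n_pix, config$n_pix))
            for (sl in seq_len(config$n_slices)) {
              vox[sl, , ] <- slices[[sl]][[chan_name]]$hu
            }
            meta <- slices[[1]][[chan_name]]
            st <- structure(list(
              voxels = vox, pixel_spacing = config$pixel_mm,
              slice_thickness = 5.0, modality = mod,
              vmi_energy = if (mod == "SECT") NA_real_ else meta$energy,
              ref_energy = meta$energy,
              lac_water_ref = meta$lac_water_ref,
              repeat_index = rep_i, seed = master_seed,
              series = series_name, size_label = size,
              phantom = phantom_layout(ph)), class = "image_stack")
            stacks[[length(stacks) + 1]] <- st
          }
        }
      }
    }
  }
  structure(stacks, class = "image_stack_set")
}

# compact, serializable description of the phantom layout for ROI placement
phantom_layout <- function(ph) {
  list(size_label = ph$size_label, body_diameter = ph$body_diameter,
       insert_id = names(ph$inserts),
       insert_x = vapply(ph$inserts, function(i) i$center_xy[1], numeric(1)),
       insert_y = vapply(ph$inserts, function(i) i$center_xy[2], numeric(1)),
       insert_radius = vapply(ph$inserts, `[[`, numeric(1), "radius"),
       insert_material = vapply(ph$inserts,
                                function(i) i$material$name, character(1)))
}

#' @export
print.image_stack <- function(x, ...) {
  cat(sprintf(
    "<image_stack> %s %s %s rep %d%s: %d x %d x %d, %.3f mm px\n",
    x$series, x$size_label, x$modality, x$repeat_index,
    if (is.na(x$vmi_energy)) "" else sprintf(" VMI %g keV", x$vmi_energy),
    dim(x$voxels)[1], dim(x$voxels)[2], dim(x$voxels)[3], x$pixel_spacing))
  invisible(x)
}
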