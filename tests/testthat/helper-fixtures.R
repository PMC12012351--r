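# shared small fixtures for fast tests

tiny_geom <- function() ct_geometry(n_views = 180, n_det = 345, det_pitch_mm = 1)

# monoenergetic "acquisition" at a single energy (delta spectrum, EID)
delta_acq <- function(energy_kev = 70, fluence = Inf) {
  sp <- structure(list(energies = energy_kev, fluence = 1,
                       kvp = energy_kev + 10, filtration_mm_al = 0),
                  class = "ct_spectrum")
  structure(list(modality = "SECT", spectra = list(sp), detector = "EID",
                 bins = NULL, fluence_per_ray = fluence),
            class = "acquisition_model")
}

# synthetic image stack with constant (or supplied) voxels, water ref at 70 keV
constant_stack <- function(value = 0, n_slices = 4, n_pix = 64, repeat_index = 1,
                           voxels = NULL) {
  vox <- if (is.null(voxels)) array(value, c(n_slices, n_pix, n_pix)) else voxels
  structure(list(voxels = vox, pixel_spacing = 1, slice_thickness = 5,
                 modality = "PCCT", vmi_energy = 70, ref_energy = 70,
                 lac_water_ref = 0.1936, repeat_index = repeat_index,
                 seed = 1, series = "calcium", size_label = "small",
                 phantom = NULL),
            class = "image_stack")
}

center_spec <- function(n_pix = 64, radius = 3, id = "ins") {
  roi_spec(id, c(n_pix %/% 2, n_pix %/% 2), radius)
}
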