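#' Write image stacks to disk (NIfTI + JSON sidecar)
#'
#' Each stack is written as a NIfTI volume (`<name>.nii.gz`, voxel order
#' rows x cols x slices) plus a JSON sidecar (`<name>.json`) carrying the
#' acquisition metadata: modality, VMI energy, repeat index, seed, series,
#' size label, pixel spacing, slice thickness, the water-LAC reference, the
#' phantom layout, and a rescale slope/intercept pair (written as 1/0; the
#' loader applies whatever pair the sidecar declares, mirroring how CT
#' rescale tags work).
#'
#' @param stacks An `image_stack_set` or list of `image_stack` objects.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the file stems written.
#' @export
write_image_stacks <- function(stacks, dir) {
  if (inherits(stacks, "image_stack")) stacks <- list(stacks)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stems <- character(0)
  for (i in seq_along(stacks)) {
    st <- stacks[[i]]
    stem <- sprintf("%s_%s_%s_%s_rep%02d",
                    st$series, st$modality, st$size_label,
                    ifelse(is.na(st$vmi_energy), "native",
                           paste0(st$vmi_energy, "keV")),
                    st$repeat_index)
    vox <- aperm(st$voxels, c(2, 3, 1))  # rows x cols x slices
    RNifti::writeNifti(RNifti::asNifti(vox, pixdim = c(st$pixel_spacing,
                                                       st$pixel_spacing,
                                                       st$slice_thickness)),
                       file.path(dir, paste0(stem, ".nii.gz")))
    meta <- list(modality = st$modality, vmi_energy = st$vmi_energy,
                 ref_energy = st$ref_energy,
                 lac_water_ref = st$lac_water_ref,
                 repeat_index = st$repeat_index, seed = st$seed,
                 series = st$series, size_label = st$size_label,
                 pixel_spacing = st$pixel_spacing,
                 slice_thickness = st$slice_thickness,
                 rescale_slope = 1, rescale_intercept = 0,
                 phantom = st$phantom)
    jsonlite::write_json(meta, file.path(dir, paste0(stem, ".json")),
                         auto_unbox = TRUE, digits = NA, null = "null")
    stems <- c(stems, stem)
  }
  invisible(stems)
}

#' Load image stacks from a directory of NIfTI + JSON sidecar pairs
#'
#' Reads every `<stem>.nii.gz`/`<stem>.json` pair, applies the sidecar's
#' rescale slope/intercept to recover HU, and restores the stack metadata.
#'
#' @param dir Directory containing the pairs.
#' @return An `image_stack_set`.
#' @export
load_image_stacks <- function(dir) {
  nii <- sort(list.files(dir, pattern = "\\.nii(\\.gz)?$", full.names = TRUE))
  if (length(nii) == 0) stop("no NIfTI volumes found in ", dir, call. = FALSE)
  stacks <- lapply(nii, function(f) {
    stem <- sub("\\.nii(\\.gz)?$", "", f)
    side <- paste0(stem, ".json")
    if (!file.exists(side)) {
      stop("missing JSON sidecar for ", basename(f), call. = FALSE)
    }
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (is.null(meta$rescale_slope) || is.null(meta$rescale_intercept)) {
      stop("sidecar for ", basename(f),
           " lacks rescale slope/intercept", call. = FALSE)
    }
    vox <- as.array(RNifti::readNifti(f))
    if (length(dim(vox)) == 2) dim(vox) <- c(dim(vox), 1)  # single slice
    vox <- vox * meta$rescale_slope + meta$rescale_intercept
    structure(list(
      voxels = aperm(vox, c(3, 1, 2)),  # slices x rows x cols
      pixel_spacing = meta$pixel_spacing,
      slice_thickness = meta$slice_thickness,
      modality = meta$modality,
      vmi_energy = if (is.null(meta$vmi_energy)) NA_real_
                   else as.numeric(meta$vmi_energy),
      ref_energy = meta$ref_energy,
      lac_water_ref = meta$lac_water_ref,
      repeat_index = meta$repeat_index, seed = meta$seed,
      series = meta$series, size_label = meta$size_label,
      phantom = meta$phantom), class = "image_stack")
  })
  structure(stacks, class = "image_stack_set")
}

#' Read ROI centers from a CSV file
#'
#' For analyzing user-supplied image series: a CSV with columns
#' `insert_id, row, col` (0-based voxel coordinates) and optionally
#' `radius_voxels` (default 3).
#'
#' @param path CSV path.
#' @return Named list of [roi_spec()] objects.
#' @export
read_centers_csv <- function(path) {
  d <- read.csv(path)
  need <- c("insert_id", "row", "col")
  if (!all(need %in% names(d))) {
    stop("centers file needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!"radius_voxels" %in% names(d)) d$radius_voxels <- 3
  out <- lapply(seq_len(nrow(d)), function(i) {
    roi_spec(d$insert_id[i], c(d$row[i], d$col[i]), d$radius_voxels[i])
  })
  names(out) <- d$insert_id
  out
}
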