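#' Convert CT numbers (HU) to linear attenuation coefficients
#'
#' By the definition of the Hounsfield unit,
#' LAC = (CT number + 1000) x LAC_water / 1000, so 0 HU maps to the water
#' LAC and -1000 HU (air) maps to 0 exactly. The map is affine and
#' invertible; [lac_to_hu()] is its inverse.
#'
#' @param hu CT numbers in HU (vectorized).
#' @param lac_water Water LAC at the image's reference energy, cm^-1 (> 0).
#' @return LAC in cm^-1.
#' @export
#' @examples
#' hu_to_lac(0, 0.1929)      # water
#' hu_to_lac(-1000, 0.1929)  # air
hu_to_lac <- function(hu, lac_water) {
  if (!is.numeric(lac_water) || lac_water <= 0) {
    stop("lac_water must be a positive LAC in cm^-1", call. = FALSE)
  }
  (hu + 1000) * lac_water / 1000
}

#' @rdname hu_to_lac
#' @param lac LAC in cm^-1.
#' @export
lac_to_hu <- function(lac, lac_water) {
  if (!is.numeric(lac_water) || lac_water <= 0) {
    stop("lac_water must be a positive LAC in cm^-1", call. = FALSE)
  }
  1000 * lac / lac_water - 1000
}

#' Circular ROI voxel mask
#'
#' All in-plane voxel offsets (dr, dc) whose center-to-center distance from
#' the ROI center is at most `radius_voxels` (center-of-voxel rule, so voxel
#' counts are reproducible: radius 1 gives 5 voxels, radius 3 gives 29).
#'
#' @param radius_voxels ROI radius in voxels (>= 1; default 3).
#' @return Integer matrix with columns `dr`, `dc`.
#' @export
roi_mask <- function(radius_voxels = 3) {
  if (radius_voxels < 1) stop("radius_voxels must be >= 1", call. = FALSE)
  r <- floor(radius_voxels)
  offs <- expand.grid(dr = -r:r, dc = -r:r)
  offs <- offs[offs$dr^2 + offs$dc^2 <= radius_voxels^2, ]
  as.matrix(offs[order(offs$dr, offs$dc), ])
}

#' ROI specification
#'
#' @param insert_id Label of the insert the ROI samples.
#' @param center `(row, col)` voxel center, 0-based.
#' @param radius_voxels ROI radius in voxels (default 3).
#' @return A `roi_spec` object.
#' @export
roi_spec <- function(insert_id, center, radius_voxels = 3) {
  stopifnot(length(center) == 2, radius_voxels >= 1)
  structure(list(insert_id = insert_id, center = as.numeric(center),
                 radius_voxels = radius_voxels), class = "roi_spec")
}

#' ROI specifications from a simulated stack's phantom layout
#'
#' Maps insert centers (mm, isocenter origin) to voxel coordinates using the
#' stack's pixel spacing and the image convention that row 0 is the top of
#' the field of view (y decreasing with row).
#'
#' @param stack An `image_stack` from [simulate_study()].
#' @param radius_voxels ROI radius in voxels (default 3).
#' @return Named list of [roi_spec()] objects, one per insert.
#' @export
roi_specs_from_phantom <- function(stack, radius_voxels = 3) {
  ph <- stack$phantom
  n <- dim(stack$voxels)[2]
  c0 <- (n - 1) / 2
  out <- lapply(seq_along(ph$insert_id), function(i) {
    col <- c0 + ph$insert_x[i] / stack$pixel_spacing
    row <- c0 - ph$insert_y[i] / stack$pixel_spacing
    roi_spec(ph$insert_id[i], c(round(row), round(col)), radius_voxels)
  })
  names(out) <- ph$insert_id
  out
}

#' Extract per-insert ROI sample sets from image stacks
#'
#' For each insert and each (slice, repeat) combination, computes the ROI
#' mean and standard deviation of the HU values (sample SD, n-1 denominator),
#' converted to LAC with the given water reference. Identical ROI coordinates
#' are used for every slice and repeat. At the defaults of 4 central slices
#' and 5 repeats this yields the 20 mean/SD data points per insert on which
#' all downstream metrics operate.
#'
#' @param stacks List of `image_stack` objects belonging to one configuration
#'   (same series/modality/size/energy, one element per repeat).
#' @param specs List of [roi_spec()]; default derives them from the phantom
#'   layout of the first stack.
#' @param lac_water_ref Water LAC (cm^-1) for the HU-to-LAC conversion;
#'   default is the reference carried by the stacks.
#' @return Named list of `roi_sample_set` objects, one per insert, each with
#'   `samples` (data.frame: slice, repeat_index, mean_lac, sd_lac),
#'   `lac_water_ref`, and `insert_id`.
#' @export
sample_rois <- function(stacks, specs = NULL, lac_water_ref = NULL) {
  if (inherits(stacks, "image_stack")) stacks <- list(stacks)
  stopifnot(length(stacks) >= 1)
  dims <- vapply(stacks, function(s) dim(s$voxels), numeric(3))
  if (any(dims != dims[, 1])) {
    stop("stacks in one configuration must share the same grid", call. = FALSE)
  }
  if (is.null(specs)) specs <- roi_specs_from_phantom(stacks[[1]])
  if (is.null(lac_water_ref)) lac_water_ref <- stacks[[1]]$lac_water_ref
  n_pix_r <- dims[2, 1]; n_pix_c <- dims[3, 1]; n_slices <- dims[1, 1]
  lapply_named <- function(x, f) setNames(lapply(x, f), names(x))
  lapply_named(specs, function(sp) {
    mask <- roi_mask(sp$radius_voxels)
    rows <- sp$center[1] + mask[, "dr"]; cols <- sp$center[2] + mask[, "dc"]
    if (any(rows < 0 | rows >= n_pix_r | cols < 0 | cols >= n_pix_c)) {
      stop("ROI for insert '", sp$insert_id, "' falls outside the image",
           call. = FALSE)
    }
    recs <- list()
    for (k in seq_along(stacks)) {
      st <- stacks[[k]]
      rep_i <- if (!is.null(st$repeat_index)) st$repeat_index else k
      for (sl in seq_len(n_slices)) {
        vals <- st$voxels[cbind(sl, rows + 1, cols + 1)]
        lac <- hu_to_lac(vals, lac_water_ref)
        recs[[length(recs) + 1]] <- data.frame(
          slice = sl, repeat_index = rep_i,
          mean_lac = mean(lac), sd_lac = sd(lac))
      }
    }
    structure(list(insert_id = sp$insert_id,
                   samples = do.call(rbind, recs),
                   lac_water_ref = lac_water_ref,
                   n_roi_voxels = nrow(mask)),
              class = "roi_sample_set")
  })
}

#' @export
print.roi_sample_set <- function(x, ...) {
  cat(sprintf("<roi_sample_set> %s: %d samples, mean LAC %.5f cm^-1\n",
              x$insert_id, nrow(x$samples), mean(x$samples$mean_lac)))
  invisible(x)
}

#' Group simulated stacks by configuration and extract ROI samples
#'
#' Splits an [simulate_study()] output by (series, modality, size,
#' VMI energy), then applies [sample_rois()] within each group.
#'
#' @param stacks An `image_stack_set`.
#' @return Nested list: `result[[config_key]][[insert_id]]` is a
#'   `roi_sample_set`; config keys are `series/modality/size/energy`.
#' @export
sample_study_rois <- function(stacks) {
  keys <- vapply(stacks, function(s) {
    paste(s$series, s$modality, s$size_label,
          ifelse(is.na(s$vmi_energy), "native", s$vmi_energy), sep = "/")
  }, character(1))
  out <- lapply(split(seq_along(stacks), keys),
                function(idx) sample_rois(stacks[idx]))
  out
}
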