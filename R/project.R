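#' Parallel-beam acquisition geometry
#'
#' Views are spread uniformly over 180 degrees; detector elements are centred
#' on a line through the isocenter. Ray (d, v) has direction
#' (cos theta_v, sin theta_v) and signed perpendicular offset s_d from the
#' isocenter. Rays are indexed detector-major: ray = d + (v - 1) * n_det.
#'
#' @param n_views Number of views over 180 degrees (default 720).
#' @param n_det Number of detector elements (default 367).
#' @param det_pitch_mm Detector element spacing in mm (default 1).
#' @return An object of class `ct_geometry`.
#' @export
ct_geometry <- function(n_views = 720, n_det = 367, det_pitch_mm = 1) {
  stopifnot(n_views >= 1, n_det >= 3, det_pitch_mm > 0)
  theta <- (seq_len(n_views) - 1) * pi / n_views
  s <- (seq_len(n_det) - (n_det + 1) / 2) * det_pitch_mm
  structure(list(n_views = n_views, n_det = n_det,
                 det_pitch_mm = det_pitch_mm, theta = theta, s = s),
            class = "ct_geometry")
}

# chord lengths (mm) of all rays through one circle; returns n_det x n_views
chord_lengths <- function(geometry, center_xy, radius) {
  off <- -center_xy[1] * sin(geometry$theta) + center_xy[2] * cos(geometry$theta)
  d <- abs(outer(geometry$s, off, "-"))
  2 * sqrt(pmax(radius^2 - d^2, 0))
}

#' Analytic per-material forward projection of a phantom
#'
#' Computes, for every ray and every distinct material in the phantom, the
#' intersection length through that material using exact circle-line chord
#' geometry (no rasterization). The background occupies the body disk minus
#' the insert holes, so its path length is the body chord minus the sum of
#' insert chords along the ray.
#'
#' @param phantom A [build_phantom()] model.
#' @param geometry A [ct_geometry()].
#' @return An object of class `ct_paths`: list with `materials` (list of
#'   [ct_material()]), `lengths_mm` (matrix, rays x materials, detector-major
#'   ray order), and `geometry`.
#' @export
forward_project <- function(phantom, geometry = ct_geometry()) {
  stopifnot(inherits(phantom, "phantom_model"), inherits(geometry, "ct_geometry"))
  n_ray <- geometry$n_det * geometry$n_views
  body <- chord_lengths(geometry, c(0, 0), phantom$body_diameter / 2)
  ins_mats <- lapply(phantom$inserts, `[[`, "material")
  mat_names <- vapply(ins_mats, `[[`, character(1), "name")
  uniq <- !duplicated(mat_names)
  materials <- c(list(phantom$background), ins_mats[uniq])
  names(materials) <- c(phantom$background$name, mat_names[uniq])
  L <- matrix(0, n_ray, length(materials))
  colnames(L) <- names(materials)
  L[, 1] <- as.vector(body)
  for (i in seq_along(phantom$inserts)) {
    ins <- phantom$inserts[[i]]
    ch <- as.vector(chord_lengths(geometry, ins$center_xy, ins$radius))
    j <- match(ins$material$name, names(materials))
    L[, j] <- L[, j] + ch
    L[, 1] <- L[, 1] - ch
  }
  # guard against tiny negative background lengths from float round-off
  L[, 1] <- pmax(L[, 1], 0)
  structure(list(materials = materials, lengths_mm = L, geometry = geometry),
            class = "ct_paths")
}
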