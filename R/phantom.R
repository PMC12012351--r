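#' Build the nested two-size phantom model
#'
#' A cylindrical water-equivalent body disk (180 mm for the small / head-size
#' configuration, 330 mm for the large / abdomen-size configuration obtained
#' by nesting the same inner disk in an outer annulus of the same material)
#' carrying up to 8 cylindrical tissue-equivalent inserts of 30 mm diameter
#' on a ring in the inner disk. The insert layout is identical in both sizes,
#' so small and large scans probe the same objects at different path lengths.
#'
#' @param size_label `"small"` (180 mm body) or `"large"` (330 mm).
#' @param inserts List of [ct_material()] for the insert ring (max 8).
#' @param background Body material (default plastic-water modelled as water).
#' @param ring_radius_mm Radius of the insert ring (default 55).
#' @param insert_radius_mm Insert radius (default 15, i.e. 30 mm diameter).
#' @param n_slices Number of axial slices the phantom represents (default 4).
#' @return An object of class `phantom_model` with `body_diameter` (mm),
#'   `background`, and `inserts` (list of `center_xy` mm, `radius` mm,
#'   `material`).
#' @export
#' @examples
#' ph <- build_phantom("small", insert_series("calcium"))
#' ph$body_diameter
build_phantom <- function(size_label = c("small", "large"), inserts,
                          background = ctqa_material("water"),
                          ring_radius_mm = 55, insert_radius_mm = 15,
                          n_slices = 4) {
  size_label <- match.arg(size_label)
  if (length(inserts) > 8) {
    stop("at most 8 inserts fit on the ring layout", call. = FALSE)
  }
  stopifnot(all(vapply(inserts, inherits, logical(1), "ct_material")))
  body_diameter <- if (size_label == "small") 180 else 330
  n <- length(inserts)
  ang <- if (n > 0) (seq_len(n) - 1) * 2 * pi / max(n, 1) + pi / 2 else numeric(0)
  ins <- lapply(seq_len(n), function(i) {
    list(center_xy = c(ring_radius_mm * cos(ang[i]),
                       ring_radius_mm * sin(ang[i])),
         radius = insert_radius_mm, material = inserts[[i]])
  })
  names(ins) <- if (!is.null(names(inserts))) names(inserts) else
    as.character(seq_len(n))
  # inserts must stay inside the inner 180 mm disk and not overlap
  if (n > 0) {
    if (ring_radius_mm + insert_radius_mm > 90) {
      stop("inserts extend beyond the inner 180 mm disk", call. = FALSE)
    }
    if (n > 1) {
      min_gap <- 2 * ring_radius_mm * sin(pi / n)
      if (min_gap < 2 * insert_radius_mm) {
        stop("inserts overlap on the ring layout", call. = FALSE)
      }
    }
  }
  structure(list(size_label = size_label, body_diameter = body_diameter,
                 background = background, inserts = ins, n_slices = n_slices),
            class = "phantom_model")
}

#' @export
print.phantom_model <- function(x, ...) {
  cat(sprintf("<phantom_model> %s (%d mm body), %d inserts, background %s\n",
              x$size_label, x$body_diameter, length(x$inserts),
              x$background$name))
  invisible(x)
}
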