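#' X-ray tube spectrum (Kramers model with aluminium filtration)
#'
#' Bremsstrahlung fluence follows the Kramers form, fluence ~ (kVp - E)/E,
#' hardened by an equivalent aluminium filter of the given thickness using the
#' shipped aluminium cross sections, and normalized to unit total fluence.
#' Characteristic lines and anode self-filtration are not modelled: only the
#' mean-energy behaviour and the hardening direction matter here.
#'
#' @param kvp Tube potential in kV (> 10).
#' @param filtration_mm_al Equivalent aluminium filtration in mm (>= 0).
#' @param bin_width Energy bin width in keV (default 1).
#' @return An object of class `ct_spectrum` with fields `energies` (bin
#'   centers, keV), `fluence` (relative, sums to 1), `kvp`, `filtration_mm_al`.
#' @export
#' @examples
#' s <- tube_spectrum(140, 7)
#' spectrum_mean_energy(s)
tube_spectrum <- function(kvp, filtration_mm_al = 0, bin_width = 1) {
  if (!is.numeric(kvp) || kvp <= 10) stop("kvp must exceed 10 kV", call. = FALSE)
  if (filtration_mm_al < 0) stop("filtration must be >= 0 mm Al", call. = FALSE)
  emax <- max(150, kvp)
  energies <- seq(10 + bin_width / 2, emax, by = bin_width)
  fl <- pmax(0, (kvp - energies) / energies)
  if (filtration_mm_al > 0) {
    al <- element_table("Al")
    mu_al <- element_mac(al, pmin(energies, max(al$energies))) * 2.699  # cm^-1
    fl <- fl * exp(-mu_al * filtration_mm_al / 10)
  }
  fl[energies >= kvp] <- 0
  tot <- sum(fl)
  if (tot <= 0) stop("spectrum has no positive fluence", call. = FALSE)
  structure(list(energies = energies, fluence = fl / tot, kvp = kvp,
                 filtration_mm_al = filtration_mm_al),
            class = "ct_spectrum")
}

#' Fluence-weighted mean energy of a spectrum
#'
#' @param spectrum A `ct_spectrum` (or any list with `energies`/`fluence`).
#' @return Mean energy in keV.
#' @export
spectrum_mean_energy <- function(spectrum) {
  fl <- spectrum$fluence
  if (!any(fl > 0)) stop("spectrum has all-zero fluence", call. = FALSE)
  sum(spectrum$energies * fl) / sum(fl)
}

#' Aluminium filtration achieving a target mean energy
#'
#' Solves for the equivalent-Al filtration at which the filtered tube spectrum
#' has the requested fluence-weighted mean energy. Used to emulate a
#' single-energy protocol whose spectrum mean energy is closest to 70 keV,
#' giving a fair comparison against 70 keV virtual monoenergetic images.
#'
#' @param kvp Tube potential in kV.
#' @param target_mean_kev Target mean energy in keV (default 70).
#' @param max_mm_al Search upper bound in mm Al (default 30).
#' @return Filtration in mm Al.
#' @export
filtration_for_mean_energy <- function(kvp, target_mean_kev = 70,
                                       max_mm_al = 30) {
  f <- function(t) spectrum_mean_energy(tube_spectrum(kvp, t)) - target_mean_kev
  lo <- f(0); hi <- f(max_mm_al)
  if (lo * hi > 0) {
    stop(sprintf("target mean %g keV not reachable at %g kVp within %g mm Al",
                 target_mean_kev, kvp, max_mm_al), call. = FALSE)
  }
  uniroot(f, c(0, max_mm_al), tol = 1e-4)$root
}

#' @export
print.ct_spectrum <- function(x, ...) {
  cat(sprintf("<ct_spectrum> %g kVp, %.2f mm Al, mean %.2f keV, %d bins\n",
              x$kvp, x$filtration_mm_al, spectrum_mean_energy(x),
              sum(x$fluence > 0)))
  invisible(x)
}
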