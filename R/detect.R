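#' Stylized acquisition models
#'
#' Three acquisition styles are modelled, capturing behaviour rather than any
#' vendor's internals:
#' * `SECT`: one polyenergetic spectrum, energy-integrating detector (EID);
#'   images receive a water beam-hardening correction only, so residual
#'   high-Z hardening persists.
#' * `DECT`: a 140/80 kVp spectrum pair, EID; basis-material decomposition is
#'   applied in the image domain, so a residual size dependence persists.
#' * `PCCT`: one spectrum read out by a photon-counting detector (PCD) in two
#'   disjoint energy bins; decomposition is applied in the projection domain
#'   and is nearly exact.
#'
#' An EID weights each detected photon by its energy; a PCD counts photons
#' per energy bin with unit weight.
#'
#' @param modality `"SECT"`, `"DECT"`, or `"PCCT"`.
#' @param fluence_per_ray Expected photons per ray in air (noise knob, a
#'   proxy for CTDIvol). `Inf` disables noise.
#' @param kvp Tube potential(s): one value (SECT/PCCT) or two (DECT,
#'   default 140/80).
#' @param filtration_mm_al Equivalent Al filtration per tube (SECT default:
#'   solved so the mean energy is 70 keV; otherwise 7 mm).
#' @param pcct_bins Two disjoint `(low, high]` keV windows for PCCT
#'   (default 20-65 and 65-140 keV).
#' @param bin_width Spectrum bin width in keV (default 2; trades spectral
#'   resolution against simulation cost).
#' @return An object of class `acquisition_model` with `spectra` (list),
#'   `detector`, `bins` (PCCT only), `fluence_per_ray`.
#' @export
#' @examples
#' acq <- acquisition_model("PCCT", fluence_per_ray = 1e7)
acquisition_model <- function(modality = c("SECT", "DECT", "PCCT"),
                              fluence_per_ray = Inf,
                              kvp = NULL, filtration_mm_al = NULL,
                              pcct_bins = list(c(20, 65), c(65, 140)),
                              bin_width = 2) {
  modality <- match.arg(modality)
  if (fluence_per_ray <= 0) stop("fluence_per_ray must be > 0", call. = FALSE)
  if (is.null(kvp)) kvp <- switch(modality, SECT = 140, PCCT = 140,
                                  DECT = c(140, 80))
  if (modality == "DECT" && length(kvp) != 2) {
    stop("DECT needs two tube potentials", call. = FALSE)
  }
  if (is.null(filtration_mm_al)) {
    filtration_mm_al <- if (modality == "SECT") {
      filtration_for_mean_energy(kvp, 70)
    } else rep(7, length(kvp))
  }
  spectra <- mapply(tube_spectrum, kvp, filtration_mm_al,
                    MoreArgs = list(bin_width = bin_width), SIMPLIFY = FALSE)
  detector <- if (modality == "PCCT") "PCD" else "EID"
  bins <- NULL
  if (modality == "PCCT") {
    stopifnot(length(pcct_bins) == 2)
    if (pcct_bins[[1]][2] > pcct_bins[[2]][1]) {
      stop("PCCT energy bins must be disjoint", call. = FALSE)
    }
    bins <- pcct_bins
  }
  structure(list(modality = modality, spectra = spectra, detector = detector,
                 bins = bins, fluence_per_ray = fluence_per_ray),
            class = "acquisition_model")
}

# channel weight vectors on the spectrum energy grid:
#   EID channel k  : w(E) = S_k(E) * E     (energy-integrating)
#   PCD bin b      : w(E) = S(E) * 1[E in bin b]
# Each channel also carries w2(E) = S(E) * E^2 (EID) for noise propagation.
acq_channels <- function(acq) {
  if (acq$detector == "EID") {
    lapply(acq$spectra, function(sp) {
      keep <- sp$fluence > 0
      list(energies = sp$energies[keep], w = sp$fluence[keep] * sp$energies[keep],
           w2 = sp$fluence[keep] * sp$energies[keep]^2,
           n = sp$fluence[keep], type = "EID",
           mean_energy = spectrum_mean_energy(sp))
    })
  } else {
    sp <- acq$spectra[[1]]
    lapply(acq$bins, function(b) {
      keep <- sp$fluence > 0 & sp$energies > b[1] & sp$energies <= b[2]
      if (!any(keep)) stop("empty PCCT energy bin", call. = FALSE)
      en <- sp$energies[keep]; fl <- sp$fluence[keep]
      list(energies = en, w = fl, w2 = fl, n = fl, type = "PCD",
           mean_energy = sum(en * fl) / sum(fl))
    })
  }
}

# expected per-ray detected quantities for one channel, per unit air fluence.
# Returns list(m1 = E[signal]/N0, m2 = E[signal^2 quanta]/N0, i0 = m1(air)).
channel_expected <- function(lengths_cm, materials, ch, chunk = 50000L) {
  mu <- vapply(materials, lac_value, numeric(length(ch$energies)),
               energy = ch$energies)
  if (is.null(dim(mu))) mu <- matrix(mu, nrow = length(ch$energies))
  n_ray <- nrow(lengths_cm)
  m1 <- numeric(n_ray); m2 <- numeric(n_ray)
  i0 <- sum(ch$w)
  for (start in seq(1L, n_ray, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n_ray)
    A <- exp(-tcrossprod(lengths_cm[idx, , drop = FALSE], mu))  # rays x E
    m1[idx] <- A %*% ch$w
    m2[idx] <- A %*% ch$w2
  }
  list(m1 = m1, m2 = m2, i0 = i0, i02 = sum(ch$w2), channel = ch)
}

#' Expected (noise-free) detected signals for a phantom
#'
#' Computes, per channel, the expected detected signal along every ray for
#' the polyenergetic Beer-Lambert model
#' I = sum_E w(E) exp(-sum_m mu_m(E) l_m), with EID weights w = S(E) E and
#' PCD bin weights w = S(E). Results are per unit air fluence and reused
#' across noise realizations.
#'
#' @param paths A [forward_project()] result.
#' @param acq An [acquisition_model()].
#' @return An object of class `ct_expected` (list of per-channel expectations
#'   plus geometry).
#' @export
detect_expected <- function(paths, acq) {
  stopifnot(inherits(paths, "ct_paths"), inherits(acq, "acquisition_model"))
  chans <- acq_channels(acq)
  L_cm <- paths$lengths_mm / 10
  exps <- lapply(chans, function(ch) channel_expected(L_cm, paths$materials, ch))
  structure(list(channels = exps, geometry = paths$geometry, acq = acq),
            class = "ct_expected")
}

#' Sample detected sinograms (optionally with quantum noise)
#'
#' With finite fluence N0, PCD bin counts are Poisson with mean
#' N0 sum_bin S(E) T(E); the EID signal is approximated as Gaussian with mean
#' N0 sum S(E) E T(E) and variance N0 sum S(E) E^2 T(E) (energy-weighted
#' Poisson quanta). With `fluence = Inf` the expected signals are returned.
#'
#' @param expected A [detect_expected()] result.
#' @param fluence Photons per ray in air; `Inf` for noise-free.
#' @param seed Integer seed for the noise realization (required when
#'   `fluence` is finite).
#' @return An object of class `ct_sinogram_set`: per channel a matrix
#'   `p` (n_det x n_views) of log line integrals -ln(I/I0), plus geometry.
#' @export
detect_sample <- function(expected, fluence = Inf, seed = NULL) {
  stopifnot(inherits(expected, "ct_expected"))
  g <- expected$geometry
  if (is.finite(fluence) && is.null(seed)) {
    stop("a seed is required for a noisy realization", call. = FALSE)
  }
  run <- function() lapply(expected$channels, function(chx) {
    if (any(chx$m1 <= 0)) {
      stop("ray with zero expected signal (fully opaque)", call. = FALSE)
    }
    if (is.finite(fluence)) {
      if (chx$channel$type == "EID") {
        sig <- rnorm(length(chx$m1), mean = fluence * chx$m1,
                     sd = sqrt(fluence * chx$m2))
        # a photon-starved EID sample can dip to zero; clamp to half a quantum
        sig <- pmax(sig, 0.5 * min(chx$channel$energies))
        p <- -log(sig / (fluence * chx$i0))
      } else {
        cnt <- rpois(length(chx$m1), fluence * chx$m1)
        cnt <- pmax(cnt, 0.5)
        p <- -log(cnt / (fluence * chx$i0))
      }
    } else {
      p <- -log(chx$m1 / chx$i0)
    }
    matrix(p, g$n_det, g$n_views)
  })
  chans <- if (is.finite(fluence)) with_seed(seed, run()) else run()
  structure(list(channels = chans, geometry = g,
                 acq = expected$acq, fluence = fluence, seed = seed),
            class = "ct_sinogram_set")
}

#' Forward-simulate detection for a phantom
#'
#' Convenience wrapper: [detect_expected()] followed by [detect_sample()]
#' at the acquisition model's fluence.
#'
#' @inheritParams detect_expected
#' @param seed Seed for the noise realization (ignored when noise is off).
#' @return A `ct_sinogram_set`.
#' @export
detect <- function(paths, acq, seed = NULL) {
  detect_sample(detect_expected(paths, acq), acq$fluence_per_ray, seed)
}
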