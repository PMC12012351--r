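# basis attenuation functions over an energy grid:
#   f1(E) = LAC of water at unit density (cm^-1), coefficient a_w dimensionless
#   f2(E) = MAC of the solute element x 1 g/cm^3, coefficient a_b in g/cm^3
basis_functions <- function(energies, basis_element,
                            water = ctqa_material("water")) {
  list(f1 = lac_value(water, energies),
       f2 = element_mac(element_table(basis_element), energies))
}

#' Projection-domain two-material basis decomposition
#'
#' Solves, ray by ray, the 2x2 nonlinear system
#' p_k = -ln( sum_E w_k(E) exp(-f1(E) t1 - f2(E) t2) / sum_E w_k(E) )
#' for the basis line integrals (t1, t2) -- water-equivalent thickness (cm)
#' and solute areal density (g/cm^2) -- given measured log signals in two
#' spectrally distinct channels. A damped Newton iteration, vectorized across
#' rays, starts from (water-equivalent thickness of channel 1, 0).
#'
#' @param sinoset A `ct_sinogram_set` with exactly two channels.
#' @param basis_element Solute basis element symbol (`"I"` or `"Ca"`).
#' @param water Water material for the first basis.
#' @param tol Convergence tolerance on the residual (default 1e-10).
#' @param max_iter Maximum Newton iterations (default 50).
#' @param t_start Optional warm start: list of two matrices (t1, t2) from a
#'   previous (e.g. noise-free) solve of the same configuration.
#' @return List of two matrices `t1`, `t2` (n_det x n_views).
#' @export
basis_decompose_projection <- function(sinoset, basis_element,
                                       water = ctqa_material("water"),
                                       tol = 1e-10, max_iter = 50,
                                       t_start = NULL) {
  stopifnot(inherits(sinoset, "ct_sinogram_set"))
  if (length(sinoset$channels) != 2) {
    stop("projection-domain decomposition needs exactly two channels",
         call. = FALSE)
  }
  chans <- acq_channels(sinoset$acq)
  e1 <- chans[[1]]$energies; e2 <- chans[[2]]$energies
  if (isTRUE(all.equal(e1, e2)) &&
      isTRUE(all.equal(chans[[1]]$w, chans[[2]]$w))) {
    stop("channels are spectrally identical; system is singular", call. = FALSE)
  }
  b1 <- basis_functions(e1, basis_element, water)
  b2 <- basis_functions(e2, basis_element, water)
  w1 <- chans[[1]]$w / sum(chans[[1]]$w)
  w2 <- chans[[2]]$w / sum(chans[[2]]$w)
  p1 <- as.vector(sinoset$channels[[1]])
  p2 <- as.vector(sinoset$channels[[2]])
  n <- length(p1)
  if (is.null(t_start)) {
    cal1 <- water_bhc_calibrate(chans[[1]], water)
    t1 <- as.vector(apply_bhc(p1, cal1)) / cal1$mu_ref
    t2 <- numeric(n)
  } else {
    t1 <- as.vector(t_start[[1]]); t2 <- as.vector(t_start[[2]])
  }
  # channel forward model and weighted-mean Jacobian, vectorized across rays
  fwd <- function(t1, t2, b, w) {
    A <- exp(-outer(t1, b$f1) - outer(t2, b$f2))
    Aw <- A * rep(w, each = length(t1))
    s <- rowSums(Aw)
    list(g = -log(s),
         j1 = as.vector(Aw %*% b$f1) / s,
         j2 = as.vector(Aw %*% b$f2) / s)
  }
  for (it in seq_len(max_iter)) {
    c1 <- fwd(t1, t2, b1, w1); c2 <- fwd(t1, t2, b2, w2)
    r1 <- c1$g - p1; r2 <- c2$g - p2
    if (max(abs(r1), abs(r2)) < tol) break
    det <- c1$j1 * c2$j2 - c1$j2 * c2$j1
    bad <- abs(det) < 1e-12 * (abs(c1$j1 * c2$j2) + abs(c1$j2 * c2$j1) + 1e-30)
    if (any(bad)) {
      stop("ill-conditioned decomposition for ", sum(bad), " ray(s)",
           call. = FALSE)
    }
    d1 <- (r1 * c2$j2 - r2 * c1$j2) / det
    d2 <- (r2 * c1$j1 - r1 * c2$j1) / det
    # damp large steps to keep the iteration inside the physical regime
    step <- pmax(abs(d1) / 60, abs(d2) / 10, 1)
    t1 <- t1 - d1 / step
    t2 <- t2 - d2 / step
  }
  g <- sinoset$geometry
  list(t1 = matrix(t1, g$n_det, g$n_views), t2 = matrix(t2, g$n_det, g$n_views))
}

#' Image-domain two-material decomposition
#'
#' Given two reconstructed attenuation images taken as estimates of the voxel
#' LAC at two effective energies, solves the voxelwise linear 2x2 system
#' mu_k = a_w f1(E_k) + a_b f2(E_k) for the basis coefficient images. Because
#' the inputs are water-corrected polyenergetic reconstructions, residual
#' high-Z beam hardening propagates into the coefficients -- the behaviour
#' that distinguishes image-domain from projection-domain decomposition.
#'
#' @param img1,img2 Reconstructed LAC images (cm^-1) of the two channels.
#' @param energy1,energy2 Effective (mean) energies of the channels, keV.
#' @param basis_element Solute basis element symbol.
#' @param water Water material for the first basis.
#' @return List of matrices `a_w` (dimensionless) and `a_b` (g/cm^3).
#' @export
basis_decompose_image <- function(img1, img2, energy1, energy2,
                                  basis_element,
                                  water = ctqa_material("water")) {
  stopifnot(identical(dim(img1), dim(img2)))
  f1 <- lac_value(water, c(energy1, energy2))
  f2 <- element_mac(element_table(basis_element), c(energy1, energy2))
  M <- matrix(c(f1[1], f1[2], f2[1], f2[2]), 2, 2)
  Minv <- solve(M)
  list(a_w = Minv[1, 1] * img1 + Minv[1, 2] * img2,
       a_b = Minv[2, 1] * img1 + Minv[2, 2] * img2)
}

#' Synthesize a virtual monoenergetic image from basis coefficients
#'
#' mu_E = a_w x mu_water(E) + a_b x MAC_basis(E), voxelwise.
#'
#' @param a_w Water-basis coefficient image (dimensionless).
#' @param a_b Solute-basis coefficient image (g/cm^3).
#' @param energy Requested monoenergetic energy in keV.
#' @param basis_element Solute basis element symbol.
#' @param water Water material.
#' @return LAC image at `energy`, cm^-1.
#' @export
synthesize_vmi <- function(a_w, a_b, energy, basis_element,
                           water = ctqa_material("water")) {
  stopifnot(length(energy) == 1)
  a_w * lac_value(water, energy) +
    a_b * element_mac(element_table(basis_element), energy)
}
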