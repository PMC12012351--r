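---
title: "Quantitative CT number evaluation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative CT number evaluation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctqa)
```

## The problem

Quantitative CT asks whether the numbers a scanner reports — CT numbers in
Hounsfield units (HU), or virtual monoenergetic image (VMI) values — can be
trusted as physical measurements of linear attenuation. `ctqa` implements the
evaluation chain for a nested two-size multi-energy phantom: a water-equivalent
disk of 18 cm (head-size) or 33 cm (abdomen-size, by adding an outer annulus)
carrying tissue-equivalent inserts — iodine in blood at 0.0/0.5/2.0/5.0/10.0/
15.0 mg/mL and calcium in water at 10/20/40/60/120/240 mg/mL. Because CT
numbers are ratios against water with an arbitrary zero, all metrics operate on
linear attenuation coefficients (LAC, cm^-1), obtained from the HU definition

LAC = (CT number + 1000) x LAC_water / 1000,

which maps 0 HU to the water LAC and -1000 HU (air) to zero attenuation.

## Theoretical ground truth

The theoretical LAC of a material is its density times its mass attenuation
coefficient (MAC), and the MAC of a mixture is the mass-fraction-weighted sum
of elemental MACs (the mixture rule). The package ships total mass attenuation
tables (photoelectric + incoherent + coherent) for H, C, N, O, Na, Mg, Al, P,
S, Cl, K, Ca, Fe and I on the standard 10–200 keV reference grid, with K-edge
points for iodine, interpolated log-log between nodes (cross sections away
from edges are near power laws, so a straight line in log-log space is the
standard scheme; no extrapolation is allowed outside the grid). The mixture
rule on these tables reproduces published compound values for liquid water
within ~0.5% across 40–150 keV. Tabulated cross sections in the kilovoltage
range carry 1–2% uncertainty, and insert densities add more, so every
theoretical LAC carries a default 2% relative uncertainty band.

Insert solutions use an additive-mass model: dissolving c mg/mL of solute
raises the density by c/1000 g/cm^3, the solute mass fraction is
concentration/density, and the base fractions are rescaled so mass is
conserved exactly. Real tissue-equivalent inserts are proprietary epoxies with
batch-specific compositions; the idealized solutions emulate their
concentration series but are *not* insert-exact, and blood is the ICRU-44
reference composition (density 1.06 g/cm^3). Conclusions about absolute
accuracy of any particular commercial insert therefore cannot be drawn from
the simulator — only the structure of the metrics and the relative behaviour
of the acquisition styles.

## The simulator

No scanner data ships with the package, so a polyenergetic parallel-beam
simulator stands in for the acquisitions. Design choices, in order of the
processing chain:

* **Geometry.** Parallel beam, 720 views over 180°, 367 detectors at 1 mm
  pitch, and analytic circle–line chord lengths per material — no
  rasterization, so beam-hardening effects are not confounded by
  discretization error. The default grid is 256 x 256 pixels over a 360 mm
  field of view.
* **Spectra.** Kramers bremsstrahlung, fluence ∝ (kVp − E)/E, hardened by
  equivalent-Al filtration and normalized; characteristic lines, anode
  effects and tin filtration are deliberately out of scope since only the
  mean energy and the hardening direction matter here. The single-energy
  (SECT) protocol uses 140 kVp with filtration solved so the mean energy is
  70 keV, matching the convention of comparing SECT against 70 keV VMI; the
  dual-energy (DECT) pair is 140/80 kVp; photon counting (PCCT) reads a
  140 kVp beam in two bins, 20–65 and 65–140 keV.
* **Detection.** An energy-integrating detector (EID) weights each photon by
  its energy; a photon-counting detector (PCD) counts per bin. With finite
  fluence N0 per ray, PCD bin counts are Poisson; the EID signal uses a
  Gaussian approximation with variance from E²-weighted quanta — accurate in
  the photon-rich regime simulated here. The default 1e7 photons/ray is a
  dose proxy giving background noise of ~5 HU (small) to ~10 HU (large
  phantom), a regime where deterministic bias dominates, as in a
  quality-assurance protocol.
* **Modality mechanics** are stylized behaviours, not vendor models:
  * *SECT*: water beam-hardening correction (BHC) only — a thickness-to-log-
    signal table for pure water, inverted by a monotone Hyman spline. Water
    reconstructs exactly; high-Z solutes retain a size- and concentration-
    dependent negative bias.
  * *DECT*: per-kVp water BHC, filtered back-projection (FBP), image-domain
    two-material decomposition at the channels' mean energies, plus one
    second-pass (Joseph–Spital-style) solute correction: the first-pass
    solute map is forward-projected and the residual between the
    polyenergetic and ideal monoenergetic responses is subtracted per ray.
    Because the correction uses biased first-pass estimates, a residual
    intermediate size dependence persists — without this second pass, an
    image-domain decomposition of water-corrected channels cannot improve on
    SECT at a matched energy, which implementation showed directly. The
    correction field is computed once per configuration from the noise-free
    expected sinogram and applied to every noise realization; it is a smooth
    low-magnitude term, and recomputing it per realization changes results
    negligibly at twice the cost.
  * *PCCT*: projection-domain basis decomposition (water + solute element),
    solved per ray by a damped, vectorized Newton iteration on the exact
    polyenergetic model (residual tolerance 1e-10, warm-started from the
    noise-free solution), then FBP of the basis sinograms. This is nearly
    exact, leaving only reconstruction-level residuals (~0.05%).
* **Reconstruction.** Ram–Lak-filtered back-projection (discrete spatial
  kernel, FFT convolution, pixel-driven compiled backprojection). The
  operator is linear and recovers a uniform disk's attenuation within 0.1%
  at the center; corners of the field of view outside detector coverage
  carry a small positive truncation bias (air reads ~-970 HU there).
* **VMI synthesis.** mu_E = a_w mu_water(E) + a_b MAC_solute(E) voxelwise;
  HU conversion uses the water LAC at the VMI energy. SECT has no unique
  theoretical LAC (its effective energy depends on the object), so SECT
  images are scaled by the water LAC at the spectrum mean energy — a
  configuration convention, not a physical truth, which is why SECT accuracy
  is never reported (only its precision and size dependence).
* **Seeds.** One master seed; every (series, size, modality, repeat, slice)
  noise stream gets a child seed by stable integer hashing, so studies are
  bit-reproducible and repeats are exchangeable by construction.

Slices of the axially uniform digital phantom differ only by noise
realization, so "4 central slices x 5 repeats" yields 20 statistically
independent ROI samples per insert — the same sample layout as the physical
protocol, without modelling z-structure the phantom does not have.

## ROI extraction

Circular ROIs of radius 3 voxels (center-of-voxel distance rule, 29 voxels —
the rule is stated so counts are reproducible) are placed at the known insert
centers; the same coordinates are used for every slice and repeat. Insert
radii (15 mm ≈ 10.7 px) comfortably exceed the ROI radius, honoring the
protocol of keeping ROIs away from insert edges. Per (slice, repeat) the ROI
mean and sample SD (n-1 denominator, chosen for unbiasedness since the
protocol leaves it unstated) of HU are converted to LAC. For user-supplied
stacks, ROI centers come from a CSV file; there is no automatic insert
detection, mirroring manual ROI placement.

## Metrics and uncertainty

All metrics act on the 20 ROI means (or SDs) of a configuration:

* **Accuracy** (PCCT/DECT only): 100 x (mean measured − theoretical)/
  theoretical, signed.
* **Precision**: coefficient of variation — sample SD of the ROI means over
  their overall mean.
* **Size dependence**: 100 x (large − small)/((large + small)/2), signed;
  the symmetrized denominator makes the metric antisymmetric under swapping
  sizes.
* **Background noise**: mean within-ROI SD on the blood (0 mg/mL iodine)
  insert, in cm^-1.

95% confidence intervals use the percentile bootstrap with 1000 resamples of
the 20-point sample set (within-ROI voxels are never resampled — the 20
slice-x-repeat points are the declared sampling unit), linear interpolation
between order statistics, and a fixed seed per metric. The percentile method
(not BCa) is used, matching the protocol being emulated; no p-values are
produced. For the size-dependence CI the two sample sets are resampled
independently.

## The statistical tier

Estimator validation needs thousands of replicates, which the physics tier
cannot provide cheaply, so a statistical generator emits ROI samples directly
from a declared model: means are theory x (1 + bias/100) + Gaussian noise
scaled by 1/sqrt(29), SDs follow the chi distribution consistent with
Gaussian voxel noise. Its default bias/noise model is a stylized stand-in
with the structure the physics tier exhibits: bias proportional to the
insert's excess attenuation over water, scaled by a path factor per size
(1 / 2.5) and modality coefficients ordered SECT (3.3) >> DECT (0.6) >> PCCT
(0.04); noise doubles with the large phantom, is 30% lower for photon
counting, and rises toward 40 keV. These coefficients were fixed once, from
the qualitative structure of the physics tier and of published multi-energy
phantom studies, and are not fitted to anything. The full VMI energy sweep
(40–130 keV) runs on this tier; the physics tier runs the 70 keV comparison
point, where the three modalities meet.

Passing tests on simulated data show that the estimators, the bootstrap, and
the processing chains behave correctly under the declared models; they do not
certify any physical scanner, vendor reconstruction, or commercial insert.

## Numerical choices and degenerate inputs

* Log-log interpolation returns tabulated values bit-exactly at grid nodes;
  energies outside a table's span are an error, never extrapolated.
* The water-BHC table (0–450 mm, 2 mm steps) must be strictly monotone or
  calibration aborts; its spline inversion is accurate to ~1e-10, with linear
  slope extension above the last node.
* Newton decomposition damps steps to 60 cm water / 10 g/cm^2 solute per
  iteration and aborts on ill-conditioned (spectrally identical) channels.
* Photon-starved detector samples are clamped at half a quantum before the
  logarithm; fully opaque rays are an error.
* Degenerate bootstrap inputs (constant data) give degenerate intervals;
  fewer than two values are an error.
* Problem sizes in the shipped tests: full-scale geometry (720 views, 256²)
  for the physics acceptance checks; 180 views / 128² for structural unit
  tests; 500 replicates for estimator recovery; 1000 trials for bootstrap
  coverage.

## Known limitations

Parallel-beam only (no fan/helical geometry), no scatter, no detector
crosstalk or pile-up, no iterative reconstruction, no tin filtration, no
dose calibration beyond the fluence knob. The DECT second-pass correction is
one iteration, not a vendor calibration. NIfTI + JSON sidecar is the on-disk
image format; DICOM metadata conventions (rescale slope/intercept) are
honored in the sidecar. The simulator reproduces the *direction and
ordering* of beam-hardening and noise effects, not the magnitudes of any
specific scanner.
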