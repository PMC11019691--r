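---
title: "Multifocus structured illumination: model, reconstruction and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multifocus structured illumination: model, reconstruction and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The imaging modality

Multifocus structured illumination microscopy (MF-SIM) combines two
ideas. Structured illumination (SIM) projects a sinusoidal excitation
pattern onto the sample; the fluorescence then carries object spatial
frequencies down-modulated by the pattern frequency into the detection
passband, and a set of phase-stepped, rotated raw images can be unmixed
computationally into a laterally super-resolved image. Multifocus
microscopy (MFM) places a diffractive multifocus grating in the emission
path so that seven focal planes, spaced 264 nm apart, are imaged
*simultaneously* as tiles on one camera frame, each receiving roughly
11% of the collected emission. Together they acquire a super-resolved
volume from a single sequence of 15 camera frames (3 pattern
orientations x 5 phases; 9 frames in two-beam mode) with no sample
motion, so the volumetric rate is limited only by exposure and camera
readout: 15 x (1 + 8.5) ms = 142.5 ms, i.e. 7.0 volumes/s at a 1 ms
exposure, or 428 ms and 2.3 volumes/s at 20 ms. An optional piezo step
of 132 nm (half the plane spacing) interleaves a second volume for finer
axial sampling at the cost of ~170 ms per translation.

This package implements the full desk-scale counterpart of such an
instrument: a physical forward model that renders raw multifocus SIM
camera frames from synthetic specimens, and the processing chain that
turns those frames back into calibrated, registered, super-resolved
volumes with the accompanying quantitative metrics.

## Forward model

**Optics.** The point-spread function is a scalar angular-spectrum
model: a uniform circular pupil with cutoff `na/lambda_em` (cycles/nm),
defocus applied as the phase `exp(2*pi*1i*kz*z)` with
`kz = sqrt((n_imm/lambda_em)^2 - kr^2)`, intensity the squared modulus
of the inverse transform. No vectorial effects, apodization factors or
index-mismatch aberrations are modelled; each defocus slice carries
equal energy (Parseval), so extended in-focus and out-of-focus objects
contribute comparable total flux, which is what makes the haze of a
widefield volume realistic. The in-focus lateral FWHM of the model
agrees with a direct Bessel-quadrature evaluation of the focal integral
to better than 2% (tested).

**Illumination.** Interference of two or three plane-wave beams. With
field amplitudes `a0` (axial beam) and `a1` (the two first orders at
lateral frequency `1/(2*period)` each), the three-beam intensity is

    I = (a0^2 + 2 a1^2)
      + 2 a1^2               cos(2*pi*u/period + 2*phi)          (fine)
      + 4 a0 a1 cos(dkz*z) * cos(  pi*u/period +   phi)          (coarse)

with `u` the coordinate along the pattern direction and
`dkz = 2*pi*n_imm/lambda_ex * (1 - cos(theta))`,
`sin(theta) = lambda_ex/(2*n_imm*period)`. The fine component at
`1/period` (237 nm by default) is z-independent and provides the lateral
resolution extension; the coarse component at half that frequency beats
axially with period `2*pi/dkz` (~1.2 um here) and is what gives
three-beam SIM its optical-sectioning advantage. Two-beam mode blocks
the axial beam (`a0 = 0`): a fully modulated, z-independent fringe at
`1/period`, five spectral orders collapse to three, and 3 phase steps
suffice. Polarization is not simulated; following the instrument's use
of circular polarization at this low pattern frequency, the modulation
depth is orientation-independent by construction. The default beam
balance `a0 = a1` equalizes the three interfering beams.

The phase step `2*pi*j/n_phases` is applied on the *fundamental*
intensity order, so order m advances by m times the step — the property
band separation relies on, asserted for m in -2..2.

**Camera.** Each plane image is scaled by its transmission efficiency
(0.11 x 7 planes; the remaining light goes to stray grating orders and
is treated as lost), placed at its tile position on a 3x3 grid with
guard gaps (centre tile = in-focus plane, two lower corners unused, a
configurable integer "jitter" per tile acts as the calibration ground
truth), then Poisson photon noise, gain conversion, Gaussian read noise
and the ADC offset/clip are applied. Noiseless mode returns the exact
expectation, which the conservation tests exploit. Rolling shutter
enters only through the timing model, not as an image artifact.

**Sequencing.** Frames are ordered phase-fastest, then orientation,
then piezo z-step, then timepoint — matching how the instrument's
pattern generator is triggered. A piezo step shifts the focal planes
*and* the illumination together relative to the sample. The full
acquisition is a pure function of the configuration and one integer
seed.

## Synthetic specimens

* `make_bead_field()` — dilute sub-diffraction beads (coverslip
  preparation when the z extent is 0), dart-throwing with a minimum
  separation. For PSF/FWHM characterization the positions can be
  snapped to the pixel grid (`snap_nm`): otherwise the trilinear
  rasterization spreads a bead over neighbouring voxels and adds ~half
  a pixel of apparent width, which is a property of the phantom, not of
  the optics being measured.
* `make_filament_network()` — persistent random walks rendered as
  Gaussian tubes of constant linear density; the first two filaments
  are seeded ~160 nm apart so a sub-diffraction crossing always exists.
  Mass deposition uses truncated, renormalized kernels, so the
  integrated density equals arc length x linear density exactly.
* `make_er_network()` — a spanning tree of tubules over random nodes
  plus flat sheet patches with punched holes, saturated at a plateau so
  the structure is one connected component above half-maximum.
* `make_two_sheet_phantom()` — two laterally disjoint, finely textured
  sheets at z = 0 and 800 nm; the out-of-focus plane above the first
  sheet's footprint isolates axial leakage for the sectioning metric.

What these phantoms do *not* emulate: motion, photobleaching and
photophysics, refractive-index structure, or the labelling statistics of
real specimens. Passing the package's tests therefore demonstrates the
correctness of the processing chain under its own forward model, not
instrument performance on real cells.

## Processing chain

**Tile calibration.** A bead field is acquired in multifocus widefield
mode while the piezo steps the whole stack through focus (the demo scans
7 x 264 nm with the beads mid-range — every tile must pass through
focus, otherwise a never-focused tile can mislock under noise). Each
tile is cropped at its nominal layout position, maximum-intensity
projected along the scan, and the integer offset to the central
reference tile is read off the peak of the normalized circular
cross-correlation (strongest peak wins when several beads produce
several). Calibration is invariant to global intensity scaling; known
integer jitters are recovered exactly in noiseless data and within 1 px
at ~1000 peak photons.

**Band separation.** Per orientation, the phase-stepped frames are
unmixed per Fourier pixel with the matrix `M[j,m] = exp(1i*m*phi_j)` —
an exact linear inversion when the number of phases equals the number of
orders (5 and 5 in three-beam mode), least squares when there are more
phases.

**Pattern estimation.** The order-1 band is correlated against the
order-0 band. Two details matter:

* both bands are first *equalized* by a regularized OTF division
  (`OTF/(OTF^2 + 0.02^2)`). Without it the asymmetric transfer
  functions of the two bands bias the correlation peak by ~0.2% of the
  wave vector — above the package's own accuracy target; with it the
  bias drops by an order of magnitude.
* the peak of the band-product spectrum is located on the grid inside a
  +-30% magnitude window and a +-10 degree wedge around the nominal
  orientation, then refined by continuous (Nelder-Mead) maximization of
  the DTFT magnitude, which resolves frequencies far below one bin.

Detection is gated on coherence — the fraction of the band-product
magnitude concentrated at the peak (about 0.5–0.9 for genuine patterns,
about 0.04 for noise; threshold 0.15). On failure the reconstruction
falls back to the nominal pattern parameters with a warning. Sparse
scenes (a handful of beads) under-constrain the fit even at high SNR,
which is why the demo's bead profile reconstructs with the calibrated
nominal pattern; structured scenes estimate reliably (wave vector to
0.04%, starting phase to ~0.01 rad in the noiseless tests).

**Generalized Wiener combination.** Each band is moved to its true
frequency position with a real-space phase ramp (exact for sub-pixel
frequencies) on a 2x upsampled grid, phase-corrected, normalized by the
modulation depth, and merged as
`sum(conj(OTF_m) B_m) / (sum |OTF_m|^2 + w^2)` followed by a triangle
apodization that reaches zero at the extended cutoff
`(1 + lambda_ex/(2 na period)) * 2 na / lambda_em`. Defaults:
`w = 0.05` (relative to the unit peak of `|OTF|^2`), upsampling 2,
output clamped at zero.

Two deliberate choices:

* *Modulation depths come from the configured pattern (in-focus
  values), not the per-plane estimates.* In multifocus data the coarse
  orders' measured depth shrinks away from the axial beat antinode;
  dividing by that small number would amplify exactly the out-of-focus
  content the beat suppresses and destroy the three-beam sectioning
  advantage. The per-plane estimates are still computed and stored as
  metadata (`mod_source = "estimate"` restores the other behaviour).
* *Optical-sectioning notch.* The order-0 band's low-frequency core is
  down-weighted by a raised-cosine notch (depth 0.92, radius = the
  orientation's order-1 offset frequency). The haze an extended
  out-of-focus structure contributes lives almost entirely in that
  core, while the modulated bands refill the low frequencies with
  content that decays with defocus — detection-side decay of the
  pattern-frequency OTF in both beam modes, plus the excitation-side
  axial beat of the coarse orders in three-beam mode. This is what
  produces the axial-contrast ordering three-beam > two-beam >
  widefield on the two-sheet phantom.

**Axial handling.** Reconstruction is strictly plane-by-plane; no axial
resolution extension is attempted (the illumination pattern cannot be
refocused during a multifocus exposure, so the classical 3D-SIM axial
reconstruction does not apply — axial *contrast*, not axial resolution,
is what improves). Interleaved piezo volumes are merged by plane
interleaving only, giving 14 planes at 132 nm from two 7-plane volumes;
no interpolation and no interleaved temporal reconstruction.

**Sub-pixel alignment.** Applied only *after* reconstruction (resampling
raw frames would disturb the sample–pattern interference). Translation
shifts between planes are found by correlation of the cross-power
spectrum with single-step upsampled-DFT refinement (1/100 px). The
cross-power is regularized as `R/(|R| + 0.3 mean|R|)`: pure phase
correlation weights noise-dominated frequencies as heavily as signal and
becomes unreliable at SNR ~10, while this intermediate weighting keeps
worst-case errors near 0.01 px there. Because the tile map has already
coarsely aligned the planes, the peak search is restricted to +-3 px;
planes that share too little structure with the reference (e.g. disjoint
content at distant z) then get a small bounded shift rather than a wild
one.

## Metrics

* `measure_fwhm()` — per bead, 1D profiles through the intensity
  maximum along x, y, z; Gaussian fit with constant offset, restricted
  to the profile's central lobe and weighted by the square root of
  intensity. Both restrictions exist because a full-profile unweighted
  Gaussian fit of a diffraction (Airy) profile lands ~5% below the
  half-maximum-crossing width; the lobe-restricted weighted fit agrees
  with the crossing measurement to well under 3% (tested against a
  crossing-interpolation oracle) while remaining exact for true
  Gaussians. Beads whose fit fails are excluded and counted; the axial
  fit needs at least 4 planes.
* `modulation_depth()` — `2 |B1| / |B0(0)|` from separated bands, with
  the order-1 peak read off the continuous transform so off-bin pattern
  frequencies lose nothing to spectral leakage. No OTF compensation: it
  reports the contrast present in the frames themselves.
* `axial_contrast()` — `1 - mean(out-of-plane over footprint) /
  max(in-plane)`, clamped to [0, 1]. The footprint is the in-plane
  structure's support, thresholded at a quarter of the maximum: a
  half-maximum threshold of a finely textured sheet selects only a few
  bright speckles and makes the leak average unstable.
* `resolution_improvement_factor()` — `1 + lambda/(2 na period)`; with
  the excitation wavelength (491 nm), NA 1.4 and the 237 nm period this
  gives the instrument's 1.74x. (The emission-based convention would
  give ~1.79; the excitation convention is the one consistent with the
  quoted figure, and the pattern frequency is indeed set by the
  excitation.)
* `axial_extent()` — `n_planes * dz` (per-plane slab coverage), the
  only convention that makes 7 x 264 nm read as 1.8 um.

## Numerical conventions and edge cases

* Unitary-direction FFTs with DC at the array centre after
  `fftshift()`; frequencies in cycles/nm; odd grid sizes give exactly
  centred, mirror-symmetric PSFs.
* Rendering uses circular FFT convolution at the tile size; because the
  sinusoidal pattern is not periodic over a tile, a Gibbs fringe hugs
  the tile border in reconstructions of extended objects. Quantitative
  statements (flat-field coefficient of variation, contrast metrics)
  are made on the interior.
* Rates are reported rounded half-up: times to 1 ms, volumetric rates
  to one decimal.
* Degenerate inputs fail loudly: duplicate phases (singular mixing),
  crops outside the frame, periods beyond the excitation pupil,
  featureless planes in alignment (zero shift with a warning),
  estimation below the coherence gate (nominal fallback with a
  warning).
* TIFF I/O uses the package's own minimal baseline codec (uncompressed
  grayscale multi-page, little-endian, `SampleFormat` IEEE float):
  32-bit float data round-trip bit-exactly, and the files open in
  ImageJ/tifffile. Voxel sizes and frame-order metadata travel in a
  JSON sidecar.

## Problem sizes

All shipped simulations run at a reduced field of view chosen so that a
full pipeline pass takes seconds: 96-pixel tiles in a 320-pixel frame
(6.2 um field at the 64.5 nm sample pixel), 6–10 beads or 4 filaments
per field, 7 planes, and single-digit z-scan lengths. Every optical and
illumination parameter keeps the reference instrument's value (NA 1.4,
491/525 nm, 100.8x, 237 nm at 41/101/161 degrees, 5 phases, 7 x 264 nm,
11%/plane, 8.5 ms readout); only the lateral extent is reduced. The
full-size 1600 x 1600 configuration is the `pipeline_config()` default
and runs the same code path.

## Known limitations

* The scalar, aberration-free PSF makes the simulated widefield
  sharper than a real instrument's (the real system's measured bead
  FWHM is broader than the diffraction limit); ratios
  (reconstruction/widefield) are therefore the meaningful quantities,
  not absolute widths.
* The axial-contrast metric compares intensities across independently
  reconstructed planes, so it is sensitive to per-plane scaling
  conventions; with the in-focus modulation normalization all planes
  share one scale, but the metric remains a coarser instrument than the
  FWHM-based ones, and for particular phantom textures the two-beam
  contrast can approach the three-beam ceiling.
* Pattern estimation needs spatial structure: sparse scenes fall back
  to nominal parameters by design.
* Richardson–Lucy deconvolution is a basic stand-in for commercial
  deconvolution packages: FFT-based circular convolution, multiplicative
  updates, no regularization.
* No multi-colour support, no dynamic (time-evolving) phantoms, no
  rolling-shutter image artifacts, no hardware control beyond the
  timing arithmetic.

## A minimal end-to-end run

```{r demo}
library(mfsim)
metrics <- run_demo("beads", outdir = "mfsim_demo", seed = 1)
# metrics$fwhm_widefield_nm, metrics$fwhm_recon_nm, metrics$lateral_ratio
metrics2 <- run_demo("two_vs_three_beam", outdir = "mfsim_demo2", seed = 1)
# metrics2$axial_contrast: three_beam > two_beam > widefield
```
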