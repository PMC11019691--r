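# Physical building blocks: optical configuration, scalar PSF/OTF model,
# and structured-illumination intensity fields.

#' Optical configuration of the microscope
#'
#' Collects the optical parameters shared by the forward simulation and the
#' reconstruction. The sample-space pixel size is always derived from the
#' camera pitch and the total magnification and cannot be set directly.
#' Defaults describe a 63x/1.4 oil objective with a 1.6x tube lens
#' (total emission magnification 100.8x), 491 nm excitation and a green
#' emission band, and a 6.5 um sCMOS pixel pitch, giving a 64.5 nm
#' sample-space pixel.
#'
#' @param na Numerical aperture (dimensionless), must satisfy
#'   `0 < na < n_imm`.
#' @param lambda_ex Excitation wavelength (nm).
#' @param lambda_em Emission wavelength (nm), must exceed `lambda_ex`
#'   (Stokes shift).
#' @param n_imm Immersion / sample refractive index.
#' @param mag_objective Objective magnification.
#' @param mag_tube Auxiliary tube-lens magnification.
#' @param camera_pitch Physical camera pixel pitch (micrometres).
#' @return An object of class `optical_config` with the derived
#'   `px_sample` (nm) field.
#' @examples
#' cfg <- optical_config()
#' cfg$px_sample  # 6500 / 100.8 = 64.48 nm
#' @export
optical_config <- function(na = 1.4, lambda_ex = 491, lambda_em = 525,
                           n_imm = 1.515, mag_objective = 63, mag_tube = 1.6,
                           camera_pitch = 6.5) {
  if (!(na > 0 && na < n_imm))
    stop("numerical aperture must satisfy 0 < na < n_imm")
  if (!(lambda_ex < lambda_em))
    stop("lambda_ex must be smaller than lambda_em (Stokes shift)")
  if (mag_objective <= 0 || mag_tube <= 0 || camera_pitch <= 0)
    stop("magnifications and camera pitch must be positive")
  cfg <- list(
    na = na, lambda_ex = lambda_ex, lambda_em = lambda_em, n_imm = n_imm,
    mag_objective = mag_objective, mag_tube = mag_tube,
    camera_pitch = camera_pitch,
    px_sample = camera_pitch * 1000 / (mag_objective * mag_tube)
  )
  structure(cfg, class = "optical_config")
}

#' Structured-illumination pattern parameters
#'
#' Describes the sinusoidal excitation pattern: its period in sample space,
#' the set of orientations, the number of phase steps and the interfering
#' beam amplitudes. In `three_beam` mode the 0th-order beam interferes with
#' the two first orders (five intensity orders, five phases required); in
#' `two_beam` mode the 0th order is blocked (`a0` is forced to zero) and
#' three phases suffice. The default amplitudes give the three interfering
#' beams equal intensity.
#'
#' @param period Pattern period in sample space (nm): the period of the
#'   fine (z-independent) intensity component, whose spatial frequency
#'   `1/period` sets the lateral resolution extension.
#' @param orientations Pattern angles in degrees. The default set
#'   (41, 101, 161) is separated by 60 degrees.
#' @param n_phases Number of equally spaced phase steps on the fundamental
#'   intensity order; must be 5 in `three_beam` mode and at least 3 in
#'   `two_beam` mode.
#' @param beam_mode `"three_beam"` or `"two_beam"`.
#' @param a0,a1 Relative field amplitudes of the 0th and the two
#'   first-order beams.
#' @return An object of class `illumination_pattern`.
#' @export
illumination_pattern <- function(period = 237,
                                 orientations = c(41, 101, 161),
                                 n_phases = NULL,
                                 beam_mode = c("three_beam", "two_beam"),
                                 a0 = 1, a1 = 1) {
  beam_mode <- match.arg(beam_mode)
  if (is.null(n_phases)) n_phases <- if (beam_mode == "three_beam") 5L else 3L
  n_phases <- as.integer(n_phases)
  if (beam_mode == "three_beam" && n_phases != 5L)
    stop("three_beam mode requires exactly 5 phase steps")
  if (beam_mode == "two_beam") {
    if (n_phases < 3L) stop("two_beam mode requires at least 3 phase steps")
    a0 <- 0
  }
  if (period <= 0) stop("pattern period must be positive")
  if (a1 <= 0) stop("first-order beam amplitude a1 must be positive")
  if (beam_mode == "three_beam" && a0 < 0) stop("a0 must be nonnegative")
  structure(list(period = period, orientations = orientations,
                 n_phases = n_phases, beam_mode = beam_mode,
                 a0 = a0, a1 = a1),
            class = "illumination_pattern")
}

# number of intensity orders per orientation (positive side), and the
# lateral frequency of intensity order 1 as a fraction of 1/period
n_orders_side <- function(pat) if (pat$beam_mode == "three_beam") 2L else 1L
order1_freq <- function(pat) {
  kf <- 1 / pat$period
  if (pat$beam_mode == "three_beam") kf / 2 else kf
}

#' Generate a scalar-diffraction 3D point-spread function
#'
#' Computes the intensity PSF of an unaberrated circular pupil by angular
#' spectrum propagation: the pupil is defined on the lateral frequency grid
#' with cutoff `na/lambda_em`, each defocus plane applies the phase
#' `exp(2 pi i kz z)` with `kz = sqrt((n_imm/lambda_em)^2 - kr^2)`, and the
#' intensity is the squared modulus of the inverse transform. The result is
#' normalized to unit total intensity and each slice is centred (the
#' intensity maximum of the in-focus slice sits at the array centre; use
#' odd lateral dimensions for exact symmetry).
#'
#' No vectorial effects or index-mismatch aberrations are modelled.
#'
#' @param cfg An [optical_config()].
#' @param shape Grid dimensions `c(ny, nx, nz)`; each must be at least 3
#'   unless `z_offsets` is given (then `nz` is implied).
#' @param voxel Spacings `c(z = dz, y = dy, x = dx)` in nm. The lateral
#'   spacing must satisfy the Nyquist bound `lambda_em / (4 na)`.
#' @param z_offsets Optional explicit defocus values (nm) replacing the
#'   centred grid implied by `shape[3]` and `voxel["z"]`.
#' @return An object of class `psf_volume`: list with `data` (ny x nx x nz
#'   array, sums to 1), `voxel`, and `z_offsets` (nm).
#' @export
generate_psf <- function(cfg, shape = c(65, 65, 9),
                         voxel = c(z = 264, y = cfg$px_sample, x = cfg$px_sample),
                         z_offsets = NULL) {
  stopifnot(inherits(cfg, "optical_config"))
  voxel <- psf_voxel(voxel)
  if (voxel["y"] != voxel["x"])
    stop("lateral voxel spacings must be isotropic")
  nyq <- cfg$lambda_em / (4 * cfg$na)
  if (voxel["x"] > nyq)
    stop(sprintf("undersampled grid: lateral spacing %.1f nm exceeds Nyquist bound %.1f nm",
                 voxel["x"], nyq))
  if (is.null(z_offsets)) {
    if (length(shape) != 3 || any(shape < 3))
      stop("shape must give at least 3 samples along each axis")
    nz <- shape[3]
    z_offsets <- (seq_len(nz) - (nz + 1) / 2) * voxel["z"]
  } else {
    if (length(shape) < 2 || any(shape[1:2] < 3))
      stop("shape must give at least 3 samples along each axis")
    nz <- length(z_offsets)
  }
  ny <- shape[1]; nx <- shape[2]

  ky <- fft_freq(ny, voxel["y"])
  kx <- fft_freq(nx, voxel["x"])
  kr2 <- outer(ky^2, kx^2, `+`)
  kmax <- cfg$na / cfg$lambda_em
  pupil <- kr2 <= kmax^2
  kz <- sqrt(pmax((cfg$n_imm / cfg$lambda_em)^2 - kr2, 0))

  data <- array(0, dim = c(ny, nx, nz))
  for (iz in seq_len(nz)) {
    field <- ifft2(pupil * exp(2i * pi * kz * z_offsets[iz]))
    data[, , iz] <- fftshift(Mod(field)^2)
  }
  data <- data / sum(data)
  structure(list(data = data, voxel = voxel, z_offsets = unname(z_offsets)),
            class = "psf_volume")
}

psf_voxel <- function(voxel) {
  if (is.null(names(voxel))) names(voxel) <- c("z", "y", "x")
  if (any(voxel <= 0)) stop("voxel spacings must be positive")
  voxel[c("z", "y", "x")]
}

#' Optical transfer function of a PSF volume
#'
#' 3D Fourier transform of the (normalized) intensity PSF, returned with DC
#' at the array centre. The zero-frequency value is exactly 1 for a
#' normalized PSF and Hermitian symmetry holds for real input.
#'
#' @param psf A `psf_volume` from [generate_psf()]. A non-normalized volume
#'   is normalized first, with a warning.
#' @return Complex array of the same dimensions, DC-centred, with
#'   attributes `k_axes` (list of cycles/nm frequency vectors, shifted
#'   layout) and `voxel`.
#' @export
psf_to_otf <- function(psf) {
  stopifnot(inherits(psf, "psf_volume"))
  d <- psf$data
  s <- sum(d)
  if (abs(s - 1) > 1e-9) {
    warning("PSF was not normalized; normalizing before transform")
    d <- d / s
  }
  # put the kernel origin at [1,1,1] so that the transform has zero phase
  # ramp, then centre DC
  dims <- dim(d)
  ish <- function(n) {
    p <- floor(n / 2)
    c(seq.int(p + 1L, n), seq_len(p))
  }
  fsh <- function(n) {
    p <- ceiling(n / 2)
    c(seq.int(p + 1L, n), seq_len(p))
  }
  d <- d[ish(dims[1]), ish(dims[2]), , drop = FALSE]
  izc <- which.min(abs(psf$z_offsets))  # in-focus slice as z origin
  d <- d[, , c(seq.int(izc, dims[3]), seq_len(izc - 1L)), drop = FALSE]
  otf <- stats::fft(d)
  otf <- otf[fsh(dims[1]), fsh(dims[2]), fsh(dims[3]), drop = FALSE]
  structure(otf,
            k_axes = list(ky = fftshift(fft_freq(dims[1], psf$voxel["y"])),
                          kx = fftshift(fft_freq(dims[2], psf$voxel["x"])),
                          kz = fftshift(fft_freq(dims[3], psf$voxel["z"]))),
            voxel = psf$voxel)
}

# Radial profile of the in-focus (z-integrated) lateral OTF as a function
# usable at arbitrary spatial frequency; used by the Wiener combination.
# Returns function(kr) -> real OTF magnitude, normalized to 1 at DC.
lateral_otf_interp <- function(cfg, n = 257, px = cfg$px_sample) {
  psf <- generate_psf(cfg, shape = c(n, n), voxel = c(z = 1, y = px, x = px),
                      z_offsets = 0)
  otf <- fft2(ifftshift(psf$data[, , 1]))
  otf <- Re(otf) / Re(otf[1, 1])
  kx <- fft_freq(n, px)
  prof <- otf[1, seq_len(floor(n / 2))]
  kk <- kx[seq_len(floor(n / 2))]
  function(kr) {
    v <- stats::approx(kk, prof, xout = abs(kr), yleft = 1, yright = 0,
                       rule = 2)$y
    v[abs(kr) > 2 * cfg$na / cfg$lambda_em] <- 0
    pmax(v, 0)
  }
}

#' Structured-illumination intensity field
#'
#' Evaluates the interference intensity of the excitation beams on a 2D
#' grid at a given defocus. In `two_beam` mode the two first-order beams
#' produce a fully modulated, z-independent fringe at spatial frequency
#' `1/period`. In `three_beam` mode the intensity contains a fine component
#' at `1/period` (z-independent) and a coarse component at `1/(2 period)`
#' whose amplitude is modulated along z as `cos(dkz * z)` with
#' `dkz = 2 pi n_imm / lambda_ex * (1 - cos(theta))`,
#' `sin(theta) = lambda_ex / (2 n_imm period)`; this axial beating is what
#' provides optical sectioning.
#'
#' The phase step `2 pi (phase_idx - 1) / n_phases` is applied on the
#' fundamental intensity order, so intensity order m advances by m times
#' the step (the phase-shift property used by band separation).
#'
#' @param pat An [illumination_pattern()].
#' @param cfg An [optical_config()]; used for the excitation pupil check
#'   and the default pixel size.
#' @param orientation_idx,phase_idx 1-based indices into the pattern's
#'   orientation and phase sets.
#' @param z Defocus (nm) at which to evaluate the field.
#' @param grid Output dimensions `c(ny, nx)`.
#' @param px Grid pixel size (nm); defaults to the sample-space pixel.
#' @return A nonnegative `ny x nx` intensity matrix.
#' @export
illumination_field <- function(pat, cfg, orientation_idx = 1, phase_idx = 1,
                               z = 0, grid = c(64, 64), px = cfg$px_sample) {
  stopifnot(inherits(pat, "illumination_pattern"),
            inherits(cfg, "optical_config"))
  if (pat$period < cfg$lambda_ex / (2 * cfg$na))
    stop(sprintf("pattern period %.1f nm lies outside the excitation pupil (limit %.1f nm)",
                 pat$period, cfg$lambda_ex / (2 * cfg$na)))
  if (orientation_idx < 1 || orientation_idx > length(pat$orientations))
    stop("orientation_idx out of range")
  if (phase_idx < 1 || phase_idx > pat$n_phases)
    stop("phase_idx out of range")

  alpha <- pat$orientations[orientation_idx] * pi / 180
  phi <- 2 * pi * (phase_idx - 1) / pat$n_phases
  kf <- 1 / pat$period
  y <- (seq_len(grid[1]) - 1) * px
  x <- (seq_len(grid[2]) - 1) * px
  # projection of position on the pattern direction
  u <- outer(y * sin(alpha), x * cos(alpha), `+`)

  a0 <- pat$a0; a1 <- pat$a1
  if (pat$beam_mode == "two_beam") {
    i2 <- 2 * a1^2 * (1 + cos(2 * pi * kf * u + phi))
    return(i2)
  }
  sin_th <- cfg$lambda_ex * kf / (2 * cfg$n_imm)
  if (sin_th >= 1) stop("pattern frequency outside the excitation pupil")
  dkz <- 2 * pi * cfg$n_imm / cfg$lambda_ex * (1 - sqrt(1 - sin_th^2))
  (a0^2 + 2 * a1^2) +
    2 * a1^2 * cos(2 * pi * kf * u + 2 * phi) +
    4 * a0 * a1 * cos(dkz * z) * cos(pi * kf * u + phi)
}

# axial beat wavenumber (rad/nm) of the three-beam coarse component
axial_beat_dkz <- function(pat, cfg) {
  sin_th <- cfg$lambda_ex / (2 * cfg$n_imm * pat$period)
  2 * pi * cfg$n_imm / cfg$lambda_ex * (1 - sqrt(1 - sin_th^2))
}
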