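# Forward model: per-plane imaging of a phantom under structured
# illumination, multiplexing of the focal planes onto one camera frame,
# and sequencing of full acquisitions including interleaved z-stepping.

#' Multifocus (plane-multiplexing) configuration
#'
#' Describes the diffractive multifocus grating and tile geometry: number
#' of simultaneously imaged focal planes, their z spacing, the fraction of
#' collected emission delivered to each plane, and where each plane's tile
#' sits on the camera frame. The default emulates a 7-plane grating with
#' 264 nm spacing delivering ~11% of the emission to each plane (the
#' remaining light goes to stray orders and is treated as lost).
#'
#' Tiles are laid out on a 3x3 grid with guard gaps; the in-focus plane
#' (z = 0) occupies the centre cell and the remaining planes fill the
#' non-corner-row cells in row-major order, leaving the two lower corners
#' unused. `jitter` holds the true per-tile offset (integer pixels) used as
#' ground truth for calibration.
#'
#' @param n_planes Number of focal planes (odd; default 7).
#' @param dz Plane spacing (nm; default 264).
#' @param plane_efficiency Per-plane fraction of the collected emission;
#'   scalar or length `n_planes`; the sum must not exceed 1.
#' @param tile_px Tile side length in camera pixels.
#' @param frame_px Camera frame side length the layout must fit in.
#' @param jitter `n_planes x 2` integer matrix of true tile offsets
#'   (row, col) in pixels, or a single number recycled; default 0.
#' @return Object of class `multifocus_config` with fields `tile_origin`
#'   (n_planes x 2, 1-based pixel origin of each tile before jitter) and
#'   `z_offsets` (nm, ascending with plane index).
#' @export
multifocus_config <- function(n_planes = 7, dz = 264,
                              plane_efficiency = 0.11,
                              tile_px = 464, frame_px = 1600,
                              jitter = 0) {
  stopifnot(n_planes >= 1, dz > 0, tile_px >= 8)
  if (length(plane_efficiency) == 1)
    plane_efficiency <- rep(plane_efficiency, n_planes)
  if (length(plane_efficiency) != n_planes)
    stop("plane_efficiency must have length 1 or n_planes")
  if (sum(plane_efficiency) > 1 + 1e-12)
    stop("plane efficiencies must sum to at most 1")
  if (n_planes > 7) stop("layouts with more than 7 planes are not supported")

  gap <- floor((frame_px - 3 * tile_px) / 4)
  if (gap < 0) stop("tile layout does not fit in the frame")
  cell_origin <- function(r, c) {
    c(gap + (r - 1) * (tile_px + gap) + 1, gap + (c - 1) * (tile_px + gap) + 1)
  }
  # centre cell for the in-focus plane; remaining cells row-major,
  # excluding the two lower corners
  cells <- list(c(1, 1), c(1, 2), c(1, 3), c(2, 1), c(2, 3), c(3, 2))
  mid <- (n_planes + 1) %/% 2
  tile_origin <- matrix(0L, n_planes, 2, dimnames = list(NULL, c("row", "col")))
  k <- 0
  for (p in seq_len(n_planes)) {
    if (p == mid) { tile_origin[p, ] <- cell_origin(2, 2) }
    else { k <- k + 1; tile_origin[p, ] <- cell_origin(cells[[k]][1], cells[[k]][2]) }
  }
  if (length(jitter) == 1) jitter <- matrix(as.integer(jitter), n_planes, 2)
  jitter <- matrix(as.integer(jitter), n_planes, 2)
  z_offsets <- (seq_len(n_planes) - mid) * dz
  structure(list(n_planes = as.integer(n_planes), dz = dz,
                 plane_efficiency = plane_efficiency, tile_px = as.integer(tile_px),
                 frame_px = as.integer(frame_px), tile_origin = tile_origin,
                 jitter = jitter, z_offsets = z_offsets),
            class = "multifocus_config")
}

#' Camera (sCMOS) configuration
#'
#' @param frame_px Sensor crop side length in pixels (default 1600).
#' @param read_noise Read noise, electrons RMS.
#' @param gain Electrons per digital unit.
#' @param offset Baseline digital units added to every pixel.
#' @param bit_depth ADC bit depth.
#' @return Object of class `camera_config`.
#' @export
camera_config <- function(frame_px = 1600, read_noise = 1.6, gain = 0.5,
                          offset = 100, bit_depth = 16) {
  stopifnot(read_noise >= 0, gain > 0, offset >= 0, bit_depth >= 8)
  structure(list(frame_px = as.integer(frame_px), read_noise = read_noise,
                 gain = gain, offset = offset, bit_depth = as.integer(bit_depth)),
            class = "camera_config")
}

#' Acquisition timing parameters
#'
#' @param exposure_ms Exposure per raw frame (ms).
#' @param readout_ms Camera readout per frame (ms; 8.5 by default — a new
#'   exposure can only start once the rolling-shutter readout completed).
#' @param n_frames_per_volume Raw frames per volume: 15 for three-beam
#'   (3 orientations x 5 phases), 9 for two-beam.
#' @param piezo_step_ms Time penalty per piezo translation (ms).
#' @param n_zsteps Interleaved piezo z-steps per timepoint (1 = none).
#' @param zstep_nm Piezo step size (nm); half the plane spacing by default.
#' @return Object of class `acquisition_timing`.
#' @export
acquisition_timing <- function(exposure_ms, readout_ms = 8.5,
                               n_frames_per_volume = 15, piezo_step_ms = 170,
                               n_zsteps = 1, zstep_nm = 132) {
  stopifnot(exposure_ms >= 0, readout_ms >= 0, piezo_step_ms >= 0,
            n_frames_per_volume >= 1, n_zsteps >= 1)
  structure(list(exposure_ms = exposure_ms, readout_ms = readout_ms,
                 n_frames_per_volume = as.integer(n_frames_per_volume),
                 piezo_step_ms = piezo_step_ms, n_zsteps = as.integer(n_zsteps),
                 zstep_nm = zstep_nm),
            class = "acquisition_timing")
}

#' Per-volume acquisition time and volumetric rate
#'
#' The camera is the bottleneck: each raw frame costs exposure plus
#' readout, all frames of all interleaved z-steps are acquired per volume,
#' and each piezo translation adds its settling penalty (no penalty
#' without z-stepping). With 15 frames, 1 ms exposure and 8.5 ms readout
#' this gives 7.0 volumes/s; with 20 ms exposure, 428 ms per volume and
#' 2.3 volumes/s.
#'
#' @param t An [acquisition_timing()].
#' @return List with `time_ms` (exact), `time_ms_rounded` (nearest ms,
#'   half up) and `rate_hz` (volumes per second, one decimal, half up).
#' @export
acquisition_time_ms <- function(t) {
  stopifnot(inherits(t, "acquisition_timing"))
  time <- t$n_zsteps * t$n_frames_per_volume * (t$exposure_ms + t$readout_ms)
  if (t$n_zsteps > 1) time <- time + t$n_zsteps * t$piezo_step_ms
  if (time <= 0) stop("degenerate timing: zero total time per volume")
  list(time_ms = time,
       time_ms_rounded = round_half_up(time),
       rate_hz = round_half_up(1000 / time, 1))
}

#' Render one focal plane's expected-photon image
#'
#' Incoherent imaging model for the camera plane focused at `plane_z`: for
#' every phantom slice the fluorophore density is multiplied by the
#' illumination intensity at that slice and convolved (circularly, via
#' FFT) with the PSF slice at the matching defocus, then all slices are
#' summed. The result is linear in the phantom density and in the
#' illumination.
#'
#' @param phantom A [density_phantom()]; its lateral grid and pixel size
#'   must match the PSF's.
#' @param psf A `psf_volume` whose `z_offsets` contain every needed
#'   defocus `z_slice - plane_z` (within 0.5 nm).
#' @param illum Illumination intensity: a single matrix (applied to all
#'   slices), a `ny x nx x nz` array matched to the phantom slices, or
#'   `NULL` for uniform unit illumination.
#' @param plane_z Focal position of this plane in sample coordinates (nm).
#' @return Matrix of expected photons per camera pixel (tile grid).
#' @export
render_plane_image <- function(phantom, psf, illum = NULL, plane_z = 0) {
  stopifnot(inherits(phantom, "density_phantom"), inherits(psf, "psf_volume"))
  dims <- dim(phantom$volume)
  if (!all(dim(psf$data)[1:2] == dims[1:2]))
    stop("resample error: phantom and PSF lateral grids differ")
  if (abs(psf$voxel["y"] - phantom$voxel["y"]) > 1e-9 ||
      abs(psf$voxel["x"] - phantom$voxel["x"]) > 1e-9)
    stop("resample error: phantom and PSF voxel sizes differ")
  img <- matrix(0, dims[1], dims[2])
  for (iz in seq_len(dims[3])) {
    sl <- phantom$volume[, , iz]
    if (!any(sl != 0)) next
    il <- if (is.null(illum)) 1
          else if (length(dim(illum)) == 3) illum[, , iz] else illum
    defocus <- phantom$z_coords[iz] - plane_z
    ipsf <- which(abs(psf$z_offsets - defocus) < 0.5)
    if (length(ipsf) == 0)
      stop(sprintf("resample error: no PSF slice at defocus %.1f nm", defocus))
    img <- img + conv2_centered(sl * il, psf$data[, , ipsf[1]])
  }
  img
}

#' Compose a multifocus camera frame from per-plane images
#'
#' Scales each plane image by its transmission efficiency, places it at
#' its tile position (nominal origin plus true jitter), then applies the
#' camera model: Poisson photon noise, conversion by the gain, additive
#' Gaussian read noise and the baseline offset, with the result rounded
#' and clipped to the bit depth. With `noise = FALSE` the expectation is
#' returned un-rounded (exact photon bookkeeping), only scaled by gain and
#' shifted by the offset.
#'
#' @param plane_images List (or `tile x tile x n_planes` array) of
#'   expected-photon images, one per plane.
#' @param mf A [multifocus_config()].
#' @param cam A [camera_config()].
#' @param seed Integer seed for the noise draw.
#' @param noise Apply Poisson + read noise (default `TRUE`).
#' @return `frame_px x frame_px` matrix in digital units.
#' @export
compose_camera_frame <- function(plane_images, mf, cam, seed = 1, noise = TRUE) {
  stopifnot(inherits(mf, "multifocus_config"), inherits(cam, "camera_config"))
  if (is.array(plane_images) && length(dim(plane_images)) == 3)
    plane_images <- lapply(seq_len(dim(plane_images)[3]),
                           function(i) plane_images[, , i])
  if (length(plane_images) != mf$n_planes)
    stop("need exactly n_planes plane images")
  if (cam$frame_px < mf$frame_px)
    stop("layout error: camera frame smaller than the tile layout frame")
  np <- cam$frame_px
  expected <- matrix(0, np, np)
  tp <- mf$tile_px
  for (p in seq_len(mf$n_planes)) {
    img <- plane_images[[p]]
    if (!all(dim(img) == c(tp, tp)))
      stop("plane images must be tile_px x tile_px")
    o <- mf$tile_origin[p, ] + mf$jitter[p, ]
    if (any(o < 1) || o[1] + tp - 1 > np || o[2] + tp - 1 > np)
      stop(sprintf("layout error: tile %d overflows the frame", p))
    rows <- o[1]:(o[1] + tp - 1); cols <- o[2]:(o[2] + tp - 1)
    expected[rows, cols] <- expected[rows, cols] + mf$plane_efficiency[p] * img
  }
  if (!noise) return(expected / cam$gain + cam$offset)
  with_seed(seed, {
    photons <- matrix(stats::rpois(np * np, pmax(expected, 0)), np, np)
    du <- photons / cam$gain + cam$offset +
      matrix(stats::rnorm(np * np, sd = cam$read_noise / cam$gain), np, np)
    pmin(pmax(round(du), 0), 2^cam$bit_depth - 1)
  })
}

#' Simulate a full multifocus SIM acquisition
#'
#' Sequences camera frames exactly as the instrument does: for each
#' timepoint and interleaved piezo z-step, it loops over pattern
#' orientations and phases (phase fastest), renders all focal planes with
#' the illumination evaluated at each phantom slice's defocus (so the
#' three-beam coarse component carries its axial modulation), and composes
#' the multifocus camera frame. A piezo z-step shifts the focal planes and
#' the illumination together by `zstep_nm` relative to the sample.
#' With `widefield = TRUE` a single uniformly illuminated frame per z-step
#' is produced (multifocus widefield mode, used for tile calibration),
#' with the illumination level matched to the pattern's mean intensity.
#'
#' @param phantom A [density_phantom()] on the tile grid.
#' @param pat An [illumination_pattern()].
#' @param cfg An [optical_config()].
#' @param mf A [multifocus_config()].
#' @param cam A [camera_config()].
#' @param timing An [acquisition_timing()] (carries `n_zsteps`/`zstep_nm`).
#' @param timepoints Number of timepoints.
#' @param seed Integer seed; the same seed gives a bit-identical
#'   acquisition.
#' @param noise Apply the camera noise model.
#' @param widefield Uniform illumination, one frame per z-step.
#' @return Object of class `raw_acquisition`: `frames` array
#'   `[y, x, frame]`, `index` data frame (timepoint, zstep, orientation,
#'   phase), the configuration objects, and `ground_truth` (true jitter,
#'   pattern parameters, per-frame plane z positions).
#' @export
simulate_acquisition <- function(phantom, pat, cfg, mf, cam, timing = NULL,
                                 timepoints = 1, seed = 1, noise = TRUE,
                                 widefield = FALSE) {
  stopifnot(inherits(phantom, "density_phantom"))
  if (is.null(timing))
    timing <- acquisition_timing(exposure_ms = 20,
                                 n_frames_per_volume =
                                   length(pat$orientations) * pat$n_phases)
  n_orient <- if (widefield) 1L else length(pat$orientations)
  n_phase <- if (widefield) 1L else pat$n_phases
  nz <- timing$n_zsteps
  n_frames <- timepoints * nz * n_orient * n_phase
  tp <- mf$tile_px
  mid <- (mf$n_planes + 1) %/% 2

  # PSF slices at every defocus the loops will need
  zsteps_nm <- (seq_len(nz) - 1) * timing$zstep_nm
  defoci <- sort(unique(round(as.vector(
    outer(phantom$z_coords,
          as.vector(outer(mf$z_offsets, zsteps_nm, `+`)), `-`)), 6)))
  psf <- generate_psf(cfg, shape = c(tp, tp),
                      voxel = c(z = 1, y = cfg$px_sample, x = cfg$px_sample),
                      z_offsets = defoci)

  mean_illum <- if (pat$beam_mode == "three_beam") pat$a0^2 + 2 * pat$a1^2
                else 2 * pat$a1^2

  frames <- array(0, dim = c(cam$frame_px, cam$frame_px, n_frames))
  index <- data.frame(frame = seq_len(n_frames), timepoint = 0L, zstep = 0L,
                      orientation = 0L, phase = 0L)
  plane_z_per_frame <- matrix(0, n_frames, mf$n_planes)
  nslice <- dim(phantom$volume)[3]

  # cache illumination per (zstep, orientation, phase) across timepoints
  illum_cache <- new.env(parent = emptyenv())
  get_illum <- function(s, o, j) {
    key <- paste(s, o, j, sep = "_")
    if (!is.null(illum_cache[[key]])) return(illum_cache[[key]])
    il <- array(0, dim = c(tp, tp, nslice))
    for (iz in seq_len(nslice)) {
      il[, , iz] <- if (widefield) matrix(mean_illum, tp, tp)
        else illumination_field(pat, cfg, o, j,
                                z = phantom$z_coords[iz] - zsteps_nm[s],
                                grid = c(tp, tp), px = cfg$px_sample)
    }
    illum_cache[[key]] <- il
    il
  }

  f <- 0L
  for (t in seq_len(timepoints)) for (s in seq_len(nz))
    for (o in seq_len(n_orient)) for (j in seq_len(n_phase)) {
      f <- f + 1L
      plane_z <- mf$z_offsets + zsteps_nm[s]
      il <- get_illum(s, o, j)
      imgs <- lapply(seq_len(mf$n_planes), function(p)
        render_plane_image(phantom, psf, il, plane_z[p]))
      frames[, , f] <- compose_camera_frame(imgs, mf, cam,
                                            seed = (seed %% 100000L) * 17000L + f,
                                            noise = noise)
      index[f, ] <- list(f, t, s, o, j)
      plane_z_per_frame[f, ] <- plane_z
    }

  structure(list(frames = frames, index = index, timing = timing,
                 cfg = cfg, pat = pat, mf = mf, cam = cam,
                 widefield = widefield,
                 ground_truth = list(jitter = mf$jitter,
                                     pattern = pat,
                                     plane_z = plane_z_per_frame,
                                     phantom_label = phantom$label)),
            class = "raw_acquisition")
}
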