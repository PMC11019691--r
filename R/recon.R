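# Plane-by-plane reconstruction of a raw multifocus SIM acquisition, the
# widefield-by-averaging companion volume, and a Richardson-Lucy
# deconvolution utility.

#' Reconstruct a super-resolved volume from a raw acquisition
#'
#' The full processing chain: every camera frame is split into its focal
#' planes with the calibrated tile map; per focal plane the frames are
#' regrouped by (orientation, phase), band-separated, the pattern
#' parameters are estimated from the data (falling back to the nominal
#' parameters with a warning if estimation fails), and the bands are
#' merged by [wiener_combine()]. Interleaved piezo z-steps are merged by
#' plane interleaving (no interpolation between planes), and the stack is
#' finally aligned by sub-pixel phase correlation. Only the first
#' timepoint is reconstructed unless `timepoint` says otherwise.
#'
#' @param raw A [simulate_acquisition()] result (or compatible object).
#' @param map A [calibrate_tile_map()] result.
#' @param timepoint Which timepoint to reconstruct.
#' @param w,apod,notch,upsample Passed to [wiener_combine()].
#' @param align Apply the final sub-pixel stack alignment.
#' @param estimate Estimate pattern parameters from the data (otherwise
#'   the nominal parameters are used directly).
#' @return Object of class `recon_volume`: `data` (upsampled
#'   `ny x nx x nz` array), `voxel` (nm), `z_coords` (nm, strictly
#'   increasing), `estimates` (per plane, per orientation), `shifts`
#'   (alignment), `wiener_w`, `apod`.
#' @export
reconstruct_volume <- function(raw, map, timepoint = 1, w = 0.05,
                               apod = "triangle", notch = NULL,
                               upsample = 2, align = TRUE, estimate = TRUE) {
  stopifnot(inherits(raw, "raw_acquisition"), inherits(map, "tile_map"))
  pat <- raw$pat
  cfg <- raw$cfg
  idx <- raw$index
  n_orient <- length(pat$orientations)
  n_phase <- pat$n_phases
  nz_steps <- sort(unique(idx$zstep))
  n_planes <- length(map$z_offsets)
  tp <- map$tile_px

  otf_fun <- lateral_otf_interp(cfg, px = cfg$px_sample)
  planes <- list(); plane_z <- c(); est_all <- list()
  for (s in nz_steps) {
    sel <- idx[idx$timepoint == timepoint & idx$zstep == s, ]
    if (nrow(sel) != n_orient * n_phase)
      stop("incomplete-group error: missing frames for z-step ", s)
    # tiles[y, x, plane, orientation, phase]
    tiles <- array(0, dim = c(tp, tp, n_planes, n_orient, n_phase))
    for (r in seq_len(nrow(sel))) {
      st <- extract_planes(raw$frames[, , sel$frame[r]], map)
      tiles[, , , sel$orientation[r], sel$phase[r]] <- st
    }
    zs_base <- sort(map$z_offsets) + (s - 1) * raw$timing$zstep_nm
    for (p in seq_len(n_planes)) {
      bands_list <- list(); est_list <- list()
      for (o in seq_len(n_orient)) {
        bands <- separate_bands(tiles[, , p, o, ])
        est <- NULL
        if (estimate)
          est <- tryCatch(
            estimate_pattern(bands, pat, cfg, orientation_idx = o,
                             otf = otf_fun),
            error = function(e) {
              warning(sprintf("plane %d orientation %d: %s; using nominal parameters",
                              p, o, conditionMessage(e)))
              NULL
            })
        if (is.null(est)) est <- nominal_estimate(pat, cfg, o)
        bands_list[[o]] <- bands
        est_list[[o]] <- est
      }
      planes[[length(planes) + 1]] <-
        wiener_combine(bands_list, est_list, cfg, pat, px = cfg$px_sample,
                       w = w, upsample = upsample, apod = apod, notch = notch,
                       otf = otf_fun)
      plane_z <- c(plane_z, zs_base[p])
      est_all[[length(est_all) + 1]] <- est_list
    }
  }
  ord <- order(plane_z)
  vol <- simplify2array(planes[ord])
  z_coords <- plane_z[ord]
  est_all <- est_all[ord]
  shifts <- NULL
  if (align && dim(vol)[3] >= 2) {
    al <- subpixel_align_stack(vol)
    vol <- al$stack
    shifts <- al$shifts
  }
  dzs <- diff(z_coords)
  structure(list(data = vol,
                 voxel = c(z = if (length(dzs)) min(dzs) else raw$mf$dz,
                           y = cfg$px_sample / upsample,
                           x = cfg$px_sample / upsample),
                 z_coords = z_coords, estimates = est_all, shifts = shifts,
                 wiener_w = w, apod = apod),
            class = "recon_volume")
}

# nominal pattern parameters as a pattern_estimate (estimation fallback)
nominal_estimate <- function(pat, cfg, orientation_idx) {
  alpha <- pat$orientations[orientation_idx] * pi / 180
  k1m <- order1_freq(pat)
  k1 <- k1m * c(sin(alpha), cos(alpha))
  mult <- if (pat$beam_mode == "three_beam") 2 else 1
  m1 <- if (pat$beam_mode == "three_beam") {
    2 * 2 * pat$a0 * pat$a1 / (pat$a0^2 + 2 * pat$a1^2)
  } else 1
  m2 <- if (pat$beam_mode == "three_beam")
    2 * pat$a1^2 / (pat$a0^2 + 2 * pat$a1^2) else NA_real_
  structure(list(wave_vector = mult * k1, k1 = k1,
                 angle_deg = pat$orientations[orientation_idx],
                 period_nm = pat$period, phase = 0, m1 = m1, m2 = m2,
                 orientation_idx = orientation_idx),
            class = "pattern_estimate")
}

#' Widefield volume by averaging the raw SIM frames
#'
#' Averaging all orientation/phase frames of a plane cancels the
#' sinusoidal modulation over complete phase cycles and leaves the
#' uniformly illuminated (widefield) image of that plane.
#'
#' @param raw A `raw_acquisition`.
#' @param map A `tile_map`.
#' @param timepoint Which timepoint to average.
#' @return List of class `widefield_volume`: `data`
#'   (`tile_px x tile_px x nz`), `voxel`, `z_coords`.
#' @export
widefield_average <- function(raw, map, timepoint = 1) {
  stopifnot(inherits(raw, "raw_acquisition"), inherits(map, "tile_map"))
  idx <- raw$index
  n_group <- length(raw$pat$orientations) * raw$pat$n_phases
  if (raw$widefield) n_group <- 1
  nz_steps <- sort(unique(idx$zstep))
  tp <- map$tile_px
  n_planes <- length(map$z_offsets)
  planes <- list(); plane_z <- c()
  for (s in nz_steps) {
    sel <- idx[idx$timepoint == timepoint & idx$zstep == s, ]
    if (nrow(sel) != n_group)
      stop("incomplete-group error: missing frames for z-step ", s)
    acc <- array(0, dim = c(tp, tp, n_planes))
    for (r in seq_len(nrow(sel)))
      acc <- acc + extract_planes(raw$frames[, , sel$frame[r]], map)
    acc <- acc / nrow(sel)
    zs_base <- sort(map$z_offsets) + (s - 1) * raw$timing$zstep_nm
    for (p in seq_len(n_planes)) {
      planes[[length(planes) + 1]] <- acc[, , p]
      plane_z <- c(plane_z, zs_base[p])
    }
  }
  ord <- order(plane_z)
  dzs <- diff(plane_z[ord])
  structure(list(data = simplify2array(planes[ord]),
                 voxel = c(z = if (length(dzs)) min(dzs) else raw$mf$dz,
                           y = raw$cfg$px_sample, x = raw$cfg$px_sample),
                 z_coords = plane_z[ord]),
            class = "widefield_volume")
}

#' Richardson-Lucy deconvolution
#'
#' Standard multiplicative Richardson-Lucy updates with FFT-based
#' (circular) convolution. Flux is conserved by the algorithm; negative
#' input values are clamped to zero with a warning.
#'
#' @param volume 2D or 3D nonnegative array.
#' @param psf A `psf_volume` (its grid must match `volume`), or a plain
#'   array kernel with origin at the array centre, normalized to sum 1.
#' @param iterations Number of RL iterations (>= 1).
#' @return Deconvolved array of the same shape.
#' @export
rl_deconvolve <- function(volume, psf, iterations = 20) {
  stopifnot(iterations >= 1)
  kern <- if (inherits(psf, "psf_volume")) psf$data else psf
  kern <- kern / sum(kern)
  if (is.matrix(volume)) volume <- array(volume, dim = c(dim(volume), 1))
  if (is.matrix(kern)) kern <- array(kern, dim = c(dim(kern), 1))
  if (!all(dim(kern) == dim(volume)))
    stop("PSF grid must match the volume grid")
  if (any(volume < 0)) {
    warning("negative input values clamped to zero")
    volume <- pmax(volume, 0)
  }
  dims <- dim(volume)
  sh <- function(n) { p <- floor(n / 2); c(seq.int(p + 1L, n), seq_len(p)) }
  k0 <- kern[sh(dims[1]), sh(dims[2]), sh(dims[3]), drop = FALSE]
  K <- stats::fft(k0)
  fconv <- function(x, Kf) Re(stats::fft(stats::fft(x) * Kf, inverse = TRUE)) / length(x)
  est <- volume
  eps <- .Machine$double.eps
  for (i in seq_len(iterations)) {
    blur <- pmax(fconv(est, K), eps)
    est <- est * fconv(volume / blur, Conj(K))
    est <- pmax(est, 0)
  }
  est
}
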