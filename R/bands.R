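# Fourier band separation of phase-stepped raw SIM frames and estimation
# of the illumination-pattern parameters (wave vector, starting phase,
# modulation depths) from the separated bands.

#' Separate the information bands of one orientation
#'
#' The phase-stepped frames of one pattern orientation mix the object
#' bands: frame j has spectrum `F_j(k) = sum_m exp(i m phi_j) B_m(k)`,
#' where band m is the object spectrum down-modulated by m times the
#' pattern frequency. With the phases known, the mixing matrix
#' `M[j, m] = exp(i m phi_j)` is inverted per pixel (exactly when the
#' number of phases equals the number of bands, by least squares when
#' there are more phases).
#'
#' @param frames `ny x nx x n_phases` array (or list of matrices) of raw
#'   frames of one orientation, ordered by phase step.
#' @param orders Integer vector of band indices; defaults to
#'   `-2..2` for 5 phases and `-1..1` for 3 phases.
#' @param phases Phase of each frame on the fundamental order (radians);
#'   defaults to `2 pi (j - 1) / n_phases`.
#' @return Object of class `band_set`: list with `orders` and `spectra`
#'   (one complex matrix per order, unshifted FFT layout).
#' @export
separate_bands <- function(frames, orders = NULL, phases = NULL) {
  if (is.list(frames)) frames <- simplify2array(frames)
  np <- dim(frames)[3]
  if (is.null(phases)) phases <- 2 * pi * (seq_len(np) - 1) / np
  if (length(phases) != np) stop("need one phase per frame")
  if (is.null(orders)) {
    h <- floor(np / 2)
    orders <- seq.int(-h, h)
    if (length(orders) > np) orders <- orders[-1]
  }
  if (length(orders) > np)
    stop("more unknown orders than phase steps")
  M <- outer(phases, orders, function(p, m) exp(1i * m * p))
  Minv <- tryCatch({
    if (length(orders) == np) solve(M) else {
      mh <- Conj(t(M))
      solve(mh %*% M) %*% mh
    }
  }, error = function(e) stop("conditioning error: phase set is degenerate"))
  Fs <- lapply(seq_len(np), function(j) fft2(frames[, , j]))
  spectra <- lapply(seq_along(orders), function(i) {
    acc <- Minv[i, 1] * Fs[[1]]
    for (j in 2:np) acc <- acc + Minv[i, j] * Fs[[j]]
    acc
  })
  names(spectra) <- as.character(orders)
  structure(list(orders = orders, spectra = spectra), class = "band_set")
}

band_order <- function(bands, m) bands$spectra[[as.character(m)]]

#' Estimate the illumination-pattern parameters from separated bands
#'
#' Locates the pattern wave vector by correlating the order-0 and order-1
#' bands. Both bands are first equalized by a regularized division with
#' the lateral OTF (which makes them near-proportional shifted copies of
#' the object spectrum and removes the bias the asymmetric transfer
#' functions would otherwise impose on the peak position); the real-space
#' product `q(x) = b1(x) * conj(b0(x))` of the equalized band images is
#' then a near-real envelope times `exp(2 pi i p . x)` where `p` is the
#' order-1 frequency offset, so the magnitude of its continuous Fourier
#' transform peaks at `p`. The peak is located on the discrete grid
#' within a window around the nominal frequency and refined by continuous
#' optimization of the DTFT magnitude. The complex amplitude at the peak
#' yields the starting phase and the modulation depth; in three-beam mode
#' the order-2 modulation is read out at twice the estimated offset.
#'
#' The reported `wave_vector` is the fine pattern frequency `1/period`
#' (cycles/nm): twice the order-1 offset in three-beam mode, equal to it
#' in two-beam mode.
#'
#' @param bands A [separate_bands()] result for one orientation.
#' @param pat The nominal [illumination_pattern()] (search prior).
#' @param cfg The [optical_config()].
#' @param orientation_idx Which orientation the bands belong to.
#' @param px Pixel size of the band images (nm).
#' @param search_frac Magnitude window around the nominal order-1
#'   frequency in which the peak is accepted (default 0.3, i.e. +-30%).
#' @param search_deg Angular half-width (degrees) of the search wedge
#'   around the nominal orientation.
#' @param min_coherence Estimation fails (error) when the correlation
#'   peak holds less than this fraction of the total band-product
#'   magnitude (a genuine pattern concentrates the product's energy at
#'   one frequency; noise spreads it).
#' @param otf Lateral OTF used for band equalization: a function of
#'   radial frequency (cycles/nm); defaults to the scalar-model OTF for
#'   `cfg`.
#' @param eq_eps Regularization of the equalizing division (relative to
#'   the DC OTF).
#' @return Object of class `pattern_estimate`: `wave_vector` `c(ky, kx)`
#'   cycles/nm, `k1` (order-1 offset vector), `angle_deg`, `period_nm`,
#'   `phase` (rad), `m1`, and `m2` (three-beam, else `NA`).
#' @export
estimate_pattern <- function(bands, pat, cfg, orientation_idx = 1,
                             px = cfg$px_sample, search_frac = 0.3,
                             search_deg = 10, min_coherence = 0.15,
                             otf = NULL, eq_eps = 0.02) {
  stopifnot(inherits(bands, "band_set"))
  if (is.null(otf)) otf <- lateral_otf_interp(cfg, px = px)
  B0 <- band_order(bands, 0)
  ny <- nrow(B0); nx <- ncol(B0)
  ky <- fft_freq(ny, px); kx <- fft_freq(nx, px)
  og <- matrix(otf(sqrt(outer(ky^2, kx^2, `+`))), ny, nx)
  eq <- og / (og^2 + eq_eps^2)
  b0 <- ifft2(B0 * eq)
  b1 <- ifft2(band_order(bands, 1) * eq)
  q <- b1 * Conj(b0)
  Q <- fft2(q)
  kmag <- sqrt(outer(ky^2, kx^2, `+`))
  k1_nom <- order1_freq(pat)
  win <- kmag >= (1 - search_frac) * k1_nom & kmag <= (1 + search_frac) * k1_nom
  # wedge around the nominal orientation (both signs of the wave vector)
  alpha_nom <- pat$orientations[orientation_idx]
  ang <- outer(ky, kx, function(a, b) atan2(a, b)) * 180 / pi
  dang <- abs(((ang - alpha_nom) %% 180 + 90) %% 180 - 90)
  win <- win & dang <= search_deg
  if (!any(win)) stop("estimation failure: search window empty")
  mag <- Mod(Q)
  mag[!win] <- 0
  pk <- which(mag == max(mag), arr.ind = TRUE)[1, ]
  if (max(mag) < min_coherence * sum(Mod(q)))
    stop("estimation failure: order-1 correlation peak below the noise floor")
  k_coarse <- c(ky[pk[1]], kx[pk[2]])
  # continuous refinement of the DTFT magnitude around the grid peak
  obj <- function(k) -Mod(dtft_at(q, k, px))
  dbin <- 1 / (max(ny, nx) * px)
  opt <- stats::optim(k_coarse, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 400))
  k1 <- opt$par
  if (sqrt(sum((k1 - k_coarse)^2)) > 1.5 * dbin) k1 <- k_coarse  # guard

  # resolve the +-p ambiguity consistently: keep the detected peak as is
  a1 <- dtft_at(q, k1, px) / sum(Mod(b0)^2)
  m1 <- 2 * Mod(a1)
  phase <- Arg(a1)
  m2 <- NA_real_
  if (pat$beam_mode == "three_beam" && "2" %in% names(bands$spectra)) {
    b2 <- ifft2(band_order(bands, 2) * eq)
    a2 <- dtft_at(b2 * Conj(b0), 2 * k1, px) / sum(Mod(b0)^2)
    m2 <- 2 * Mod(a2)
  }
  mult <- if (pat$beam_mode == "three_beam") 2 else 1
  wv <- mult * k1
  if (m1 > 1.5) { warning("modulation depth clipped to 1.5"); m1 <- 1.5 }
  structure(list(wave_vector = wv, k1 = k1,
                 angle_deg = (atan2(wv[1], wv[2]) * 180 / pi) %% 180,
                 period_nm = 1 / sqrt(sum(wv^2)),
                 phase = phase, m1 = m1, m2 = m2,
                 orientation_idx = orientation_idx),
            class = "pattern_estimate")
}
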