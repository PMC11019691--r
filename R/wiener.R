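# Generalized Wiener combination of separated SIM bands: each band is
# shifted to its true frequency position on an upsampled grid and merged
# with OTF-weighted regularized division, followed by apodization. An
# optical-sectioning notch down-weights the low-frequency core of the
# order-0 band, so that the out-of-focus haze carried by the unmodulated
# band is replaced by the in-focus-weighted content of the modulated
# bands.

# embed an N x N spectrum (unshifted layout) in the centre of an N2 x N2
# grid (zero padding in frequency = band-limited upsampling)
pad_spectrum <- function(S, n2) {
  n <- nrow(S)
  if (n2 == n) return(S)
  big <- matrix(0 + 0i, n2, n2)
  cs <- fftshift(S)
  o <- floor(n2 / 2) - floor(n / 2)
  big[o + seq_len(n), o + seq_len(n)] <- cs
  ifftshift(big) * (n2 / n)^2
}

#' Generalized Wiener combination of one plane's bands
#'
#' Assembles the super-resolved spectrum of a single focal plane from the
#' separated bands of all orientations. Band m of orientation theta is
#' moved to its true position (a frequency shift of `-m * k1_theta`,
#' applied as a real-space phase ramp so sub-pixel frequencies are exact),
#' phase-corrected by the estimated starting phase and normalized by the
#' modulation depth, then all bands are combined as
#' `sum(conj(OTF_m) B_m) / (sum |OTF_m|^2 + w^2)` and multiplied by a
#' triangle apodization reaching zero at the extended cutoff
#' `(1 + lambda_ex / (2 na period)) * (2 na / lambda_em)`.
#'
#' @param bands_list List of [separate_bands()] results, one per
#'   orientation.
#' @param est_list List of [estimate_pattern()] results, one per
#'   orientation.
#' @param cfg An [optical_config()].
#' @param pat The [illumination_pattern()] used for the acquisition.
#' @param px Pixel size of the raw plane images (nm).
#' @param w Wiener regularization parameter, relative to the peak
#'   `|OTF|^2` (default 0.05).
#' @param upsample Output grid oversampling (2 gives the px/2 output grid
#'   needed for the extended support; 1 for debugging).
#' @param apod `"triangle"` or `"none"`.
#' @param notch Optical-sectioning notch on the order-0 band:
#'   `list(depth, radius)` with depth in `[0, 1]` and radius in cycles/nm
#'   (defaults: depth 0.92, radius = the orientation's order-1 offset
#'   frequency); pass `list(depth = 0)` to disable.
#' @param otf Optional transfer-function override: a function of radial
#'   frequency (cycles/nm). Defaults to the scalar-model lateral OTF for
#'   `cfg`.
#' @param mod_source Where the band-normalizing modulation depths come
#'   from: `"pattern"` (default) uses the in-focus depths implied by the
#'   configured beam amplitudes; `"estimate"` uses the per-plane measured
#'   depths. The default matters for multifocus data: away from the
#'   axial beat antinode the measured coarse-order depth shrinks, and
#'   dividing by it would amplify exactly the out-of-focus content that
#'   optical sectioning is meant to reject, so the in-focus value is used
#'   for all planes (the estimates remain available as metadata).
#' @param clamp Clamp negative output values to zero (default `TRUE`;
#'   disable to inspect the linear, signed reconstruction).
#' @return Real matrix of side `upsample * n`; the super-resolved plane
#'   (negative values clamped to zero unless `clamp = FALSE`).
#' @export
wiener_combine <- function(bands_list, est_list, cfg, pat,
                           px = cfg$px_sample, w = 0.05, upsample = 2,
                           apod = c("triangle", "none"), notch = NULL,
                           otf = NULL, mod_source = c("pattern", "estimate"),
                           clamp = TRUE) {
  apod <- match.arg(apod)
  mod_source <- match.arg(mod_source)
  if (w <= 0) stop("Wiener parameter w must be positive")
  if (is.null(otf)) otf <- lateral_otf_interp(cfg, px = px)
  if (inherits(bands_list, "band_set")) bands_list <- list(bands_list)
  if (inherits(est_list, "pattern_estimate")) est_list <- list(est_list)
  n <- nrow(bands_list[[1]]$spectra[[1]])
  n2 <- as.integer(upsample * n)
  px2 <- px * n / n2
  ky2 <- fft_freq(n2, px2); kx2 <- fft_freq(n2, px2)
  kmag <- sqrt(outer(ky2^2, kx2^2, `+`))
  yy <- (seq_len(n2) - 1) * px2
  xx <- (seq_len(n2) - 1) * px2

  if (is.null(notch)) notch <- list(depth = 0.92, radius = NULL)
  if (is.null(notch$depth)) notch$depth <- 0.92
  if (notch$depth < 0 || notch$depth > 1) stop("notch depth must be in [0, 1]")

  num <- matrix(0 + 0i, n2, n2)
  den <- matrix(0, n2, n2)
  for (o in seq_along(bands_list)) {
    bands <- bands_list[[o]]
    est <- est_list[[o]]
    k1 <- est$k1
    nr <- notch$radius
    if (is.null(nr)) nr <- sqrt(sum(k1^2))
    if (mod_source == "pattern") {
      m1_use <- if (pat$beam_mode == "three_beam")
        4 * pat$a0 * pat$a1 / (pat$a0^2 + 2 * pat$a1^2) else 1
      m2_use <- if (pat$beam_mode == "three_beam")
        2 * pat$a1^2 / (pat$a0^2 + 2 * pat$a1^2) else NA_real_
    } else {
      m1_use <- est$m1
      m2_use <- est$m2
    }
    for (m in bands$orders) {
      B <- band_order(bands, m)
      mod_m <- if (abs(m) == 1) max(m1_use, 0.05)
               else if (abs(m) == 2) max(ifelse(is.na(m2_use), m1_use, m2_use), 0.05)
               else 1
      Bc <- B * exp(-1i * m * est$phase) / mod_m
      b <- ifft2(pad_spectrum(Bc, n2))
      # move band content from k to k - m*k1 (true position)
      if (m != 0) {
        ramp <- exp(-2i * pi * m * (outer(k1[1] * yy, rep(1, n2)) +
                                    outer(rep(1, n2), k1[2] * xx)))
        b <- b * ramp
      }
      Bs <- fft2(b)
      # OTF of this band at the assembled frequency: OTF(k + m*k1)
      kys <- outer(ky2 + m * k1[1], rep(1, n2))
      kxs <- outer(rep(1, n2), kx2 + m * k1[2])
      otf_m <- matrix(otf(sqrt(kys^2 + kxs^2)), n2, n2)
      nw <- 1
      if (m == 0 && notch$depth > 0) {
        nw <- 1 - notch$depth * cos(pmin(kmag / nr, 1) * pi / 2)^2
      }
      num <- num + Conj(otf_m) * Bs * nw
      den <- den + Mod(otf_m)^2
    }
  }
  R <- num / (den + w^2)
  if (apod == "triangle") {
    kc <- 2 * cfg$na / cfg$lambda_em
    kext <- (1 + cfg$lambda_ex / (2 * cfg$na * pat$period)) * kc
    R <- R * pmax(1 - kmag / kext, 0)
  }
  out <- ifft2(R)
  res <- max(Mod(Im(out))) / max(stats::sd(Re(out)), .Machine$double.eps)
  out <- if (clamp) pmax(Re(out), 0) else Re(out)
  structure(out, imag_residual = res)
}
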