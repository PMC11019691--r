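# Scalar PSF/OTF model and structured-illumination fields.

test_that("optical configuration derives the pixel size and enforces physics", {
  cfg <- optical_config()
  expect_equal(cfg$px_sample, 6500 / 100.8)
  expect_error(optical_config(na = 1.6, n_imm = 1.515), "na")
  expect_error(optical_config(lambda_ex = 600, lambda_em = 525), "Stokes")
})

test_that("illumination pattern validates its invariants", {
  pat <- illumination_pattern()
  expect_equal(diff(pat$orientations), c(60, 60))
  expect_equal(pat$n_phases, 5L)
  expect_error(illumination_pattern(n_phases = 3, beam_mode = "three_beam"))
  p2 <- illumination_pattern(beam_mode = "two_beam", a0 = 0.7)
  expect_identical(p2$a0, 0)   # 0th order blocked in two-beam mode
  expect_error(illumination_pattern(n_phases = 2, beam_mode = "two_beam"))
})

test_that("PSF is normalized, centred and mirror-symmetric on an odd grid", {
  cfg <- optical_config()
  psf <- generate_psf(cfg, shape = c(65, 65, 5), voxel = c(z = 264, y = 64.5, x = 64.5))
  expect_equal(sum(psf$data), 1, tolerance = 1e-12)
  focus <- psf$data[, , 3]
  expect_equal(unname(which(focus == max(focus), arr.ind = TRUE)[1, ]), c(33, 33))
  expect_lt(max(abs(focus - focus[65:1, 65:1])), 1e-15)
  # in-focus value is the global maximum
  expect_equal(max(psf$data), max(focus))
  expect_error(generate_psf(cfg, shape = c(65, 65, 2)), "3 samples")
  expect_error(generate_psf(cfg, shape = c(65, 65, 5),
                            voxel = c(z = 264, y = 200, x = 200)), "undersampled")
})

test_that("focal-plane lateral FWHM matches the Bessel-quadrature oracle", {
  cfg <- optical_config()
  psf <- generate_psf(cfg, shape = c(129, 129), voxel = c(z = 1, y = 32, x = 32),
                      z_offsets = 0)
  prof <- psf$data[65, , 1]
  x <- ((1:129) - 65) * 32
  half <- max(prof) / 2
  above <- which(prof >= half)
  i1 <- min(above); i2 <- max(above)
  lf <- stats::approx(prof[c(i1 - 1, i1)], x[c(i1 - 1, i1)], xout = half)$y
  rf <- stats::approx(prof[c(i2 + 1, i2)], x[c(i2 + 1, i2)], xout = half)$y
  oracle <- airy_fwhm_oracle(cfg$na, cfg$lambda_em)
  expect_lt(abs((rf - lf) - oracle) / oracle, 0.02)
})

test_that("OTF has unit DC, Hermitian symmetry and the analytic support", {
  cfg <- optical_config()
  psf <- generate_psf(cfg, shape = c(129, 129, 5), voxel = c(z = 264, y = 32, x = 32))
  otf <- psf_to_otf(psf)
  ka <- attr(otf, "k_axes")
  c0 <- which(ka$ky == 0); z0 <- which(ka$kz == 0)
  expect_equal(otf[c0, c0, z0], 1 + 0i, tolerance = 1e-12)
  # OTF(-k) = conj(OTF(k)) for real input; the centred grid mirrors index
  # j to 2*c0 - j
  for (pick in list(c(40, 80, 2), c(70, 30, 4), c(90, 91, 3))) {
    a <- otf[pick[1], pick[2], pick[3]]
    b <- otf[2 * c0 - pick[1], 2 * c0 - pick[2], 2 * z0 - pick[3]]
    expect_equal(a, Conj(b), tolerance = 1e-10)
  }
  prof <- Mod(otf[c0, , z0])
  idx <- which(prof > 1e-3)
  support <- max(abs(ka$kx[idx]))
  expect_lt(abs(support - 2 * cfg$na / cfg$lambda_em) / (2 * cfg$na / cfg$lambda_em),
            0.05)
  # non-normalized input is normalized with a warning
  psf$data <- psf$data * 3
  expect_warning(psf_to_otf(psf), "normaliz")
})

test_that("two-beam field is fully modulated with the expected mean", {
  cfg <- optical_config()
  pat <- illumination_pattern(beam_mode = "two_beam", a1 = 1.3)
  # orientation along x with an integer number of periods in the window
  pat$orientations <- c(0, 60, 120)
  px <- pat$period / 16
  il <- illumination_field(pat, cfg, 1, 1, grid = c(4, 128), px = px)
  expect_equal(mean(il), 2 * 1.3^2, tolerance = 1e-12)
  expect_equal((max(il) - min(il)) / (max(il) + min(il)), 1, tolerance = 1e-9)
  expect_error(illumination_field(illumination_pattern(period = 170), cfg),
               "pupil")
})

test_that("three-beam field has five spectral peaks and the 237 nm fine period", {
  cfg <- optical_config()
  pat <- illumination_pattern()
  pat$orientations <- c(0, 60, 120)
  px <- pat$period / 8  # 16 fine periods across 128 samples, axis-aligned
  il <- illumination_field(pat, cfg, 1, 1, z = 0, grid = c(4, 128), px = px)
  sp <- Mod(stats::fft(il[1, ]))
  peaks <- which(sp > 1e-9 * max(sp))
  expect_length(peaks, 5)  # orders 0, +-1, +-2
  # fine-component frequency at the default (non-commensurate) sampling
  pat2 <- illumination_pattern()
  il2 <- illumination_field(pat2, cfg, 1, 1, z = 0, grid = c(192, 192))
  sp2 <- Mod(stats::fft(il2))
  k <- fft_freq(192, cfg$px_sample)
  km <- sqrt(outer(k^2, k^2, `+`))
  fine <- which(km > 0.8 / 237 & km < 1.2 / 237)
  pk <- fine[which.max(sp2[fine])]
  dbin <- 1 / (192 * cfg$px_sample)
  expect_lt(abs(km[pk] - 1 / 237), dbin + 1e-12)
})

test_that("phase stepping advances order m by m times the step", {
  cfg <- optical_config()
  pat <- illumination_pattern()
  pat$orientations <- c(0, 60, 120)
  px <- pat$period / 8
  base <- illumination_field(pat, cfg, 1, 1, z = 130, grid = c(4, 128), px = px)
  f0 <- stats::fft(base[1, ])
  delta <- 2 * pi / 5
  stepped <- illumination_field(pat, cfg, 1, 2, z = 130, grid = c(4, 128), px = px)
  f1 <- stats::fft(stepped[1, ])
  # orders m = -2..2 sit at bins 1 -/+ 16 m (coarse = 8): coarse at +-8,
  # fine at +-16 in a 128-sample window with period 16 px (fine)
  for (m in -2:2) {
    bin <- (m * 8) %% 128 + 1
    if (Mod(f0[bin]) < 1e-9) next
    expect_equal(f1[bin] / f0[bin], exp(1i * m * delta), tolerance = 1e-9)
  }
})

test_that("modulation is uniform across orientations and energy is phase-invariant", {
  cfg <- optical_config()
  pat <- illumination_pattern()
  depth <- function(o, j) {
    il <- illumination_field(pat, cfg, o, j, z = 0, grid = c(160, 160))
    (max(il) - min(il)) / (max(il) + min(il))
  }
  d <- sapply(1:3, depth, j = 1)
  expect_lt(max(d) - min(d), 1e-6)
  means <- sapply(1:5, function(j) {
    pat0 <- pat; pat0$orientations <- c(0, 60, 120)
    mean(illumination_field(pat0, cfg, 1, j, z = 0, grid = c(4, 160),
                            px = pat$period / 16)[1, ])
  })
  expect_lt(max(means) - min(means), 1e-9)
})
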