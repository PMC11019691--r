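# Tile-map calibration from bead z-scans and sub-pixel stack alignment.

widefield_bead_stack <- function(jitter, seed = 1, noise = FALSE,
                                 brightness = 3e5, n_beads = 6) {
  cfg <- small_cfg()
  px <- cfg$px_sample
  tp <- 64
  field <- tp * px
  mf <- multifocus_config(tile_px = tp, frame_px = 220, jitter = jitter)
  gain <- 1
  cam <- camera_config(frame_px = 220, gain = gain, offset = 0,
                       read_noise = if (noise) 1.6 else 0)
  em <- make_bead_field(n_beads, c(field, field, 0), min_sep = 900,
                        seed = seed + 50, margin = 10 * px)
  em$positions[, 3] <- 3 * 264  # mid-range: scan covers every plane's focus
  ph <- rasterize_emitters(em, c(tp, tp, 1), c(z = 264, y = px, x = px),
                           z_coords = 3 * 264)
  ph$volume <- ph$volume * brightness / 1000
  tim <- acquisition_timing(exposure_ms = 10, n_frames_per_volume = 1,
                            n_zsteps = 7, zstep_nm = 264)
  list(mf = mf,
       raw = simulate_acquisition(ph, illumination_pattern(), cfg, mf, cam,
                                  tim, seed = seed, noise = noise,
                                  widefield = TRUE))
}

test_that("calibration recovers zero and known integer jitters exactly", {
  s0 <- widefield_bead_stack(jitter = 0)
  m0 <- calibrate_tile_map(s0$raw, s0$mf)
  expect_true(all(m0$offset == 0))

  jit <- matrix(as.integer(c(2, -1, 0, -3, 1, 2, -2,
                             -1, 2, 1, 0, -2, 3, 1)), 7, 2)
  s1 <- widefield_bead_stack(jitter = jit)
  m1 <- calibrate_tile_map(s1$raw, s1$mf)
  expect_equal(m1$offset, sweep(jit, 2, jit[4, ]),
               ignore_attr = TRUE)  # relative to reference tile
})

test_that("calibration holds within 1 px under Poisson noise over 20 seeds", {
  jit <- matrix(as.integer(c(3, -2, 1, 0, -1, 2, -3,
                             2, 1, -2, 0, 3, -1, 1)), 7, 2)
  worst <- 0
  for (s in 1:20) {
    st <- widefield_bead_stack(jitter = jit, seed = s, noise = TRUE,
                               brightness = 3e5)
    m <- calibrate_tile_map(st$raw, st$mf)
    err <- abs(m$offset - sweep(jit, 2, jit[4, ]))
    worst <- max(worst, max(err))
  }
  expect_lte(worst, 1)
})

test_that("calibration is invariant to global intensity scaling", {
  jit <- matrix(0L, 7, 2); jit[2, ] <- c(2L, -3L)
  st <- widefield_bead_stack(jitter = jit)
  m1 <- calibrate_tile_map(st$raw, st$mf)
  st$raw$frames <- st$raw$frames * 37.5
  m2 <- calibrate_tile_map(st$raw, st$mf)
  expect_identical(m1$offset, m2$offset)
})

test_that("plane extraction is a pure crop in ascending z order", {
  mf <- multifocus_config(tile_px = 8, frame_px = 36)
  cam <- camera_config(frame_px = 36, gain = 1, offset = 0, read_noise = 0)
  imgs <- lapply(1:7, function(p) matrix(p * 10, 8, 8))
  fr <- compose_camera_frame(imgs, mf, cam, noise = FALSE)
  map <- structure(list(origin = mf$tile_origin, offset = matrix(0L, 7, 2),
                        tile_px = 8L, z_offsets = mf$z_offsets, reference = 4L),
                   class = "tile_map")
  st <- extract_planes(fr, map)
  for (p in 1:7) expect_true(all(abs(st[, , p] - 0.11 * p * 10) < 1e-12))
  bad <- map; bad$origin[1, ] <- c(-5L, 1L)
  expect_error(extract_planes(fr, bad), "bounds")
})

test_that("noiseless compose-then-extract reproduces scaled planes exactly", {
  fx <- filament_fixture()
  raw <- fx$raw
  st <- extract_planes(raw$frames[, , 3], fx$map)
  expect_equal(dim(st), c(96, 96, 7))
  # planes are nonnegative scaled photon images (gain 1, offset 0)
  expect_true(all(st >= 0))
})

test_that("sub-pixel alignment recovers known shifts and is idempotent", {
  set.seed(4)
  base <- matrix(0, 96, 96)
  for (i in 1:15) base[sample(20:76, 1), sample(20:76, 1)] <- stats::runif(1, 0.5, 1)
  g <- outer(exp(-((-47:48))^2 / 12), exp(-((-47:48))^2 / 12))
  base <- Re(stats::fft(stats::fft(base) * stats::fft(ifftshift(g / sum(g))),
                        inverse = TRUE)) / length(base)

  expect_equal(phase_correlation_shift(base, base), c(0, 0))

  mov <- fourier_shift(base, c(0.30, -0.70))
  sh <- phase_correlation_shift(base, mov)
  expect_lt(max(abs(sh - c(0.30, -0.70))), 0.05)

  stack <- array(0, c(96, 96, 3))
  stack[, , 1] <- fourier_shift(base, c(-0.4, 0.55))
  stack[, , 2] <- base
  stack[, , 3] <- mov
  al <- subpixel_align_stack(stack)
  expect_equal(al$shifts[2, ], c(dy = 0, dx = 0))
  expect_lt(max(abs(al$shifts[3, ] - c(0.30, -0.70))), 0.05)
  al2 <- subpixel_align_stack(al$stack)
  expect_lt(max(abs(al2$shifts)), 0.05)

  flat <- array(1, c(32, 32, 2))
  expect_warning(subpixel_align_stack(flat), "featureless")
})

test_that("shift recovery stays below 0.1 px at SNR 10 over 50 random cases", {
  set.seed(99)
  base <- matrix(stats::runif(96 * 96), 96, 96)
  k <- fft_freq(96)
  lp <- exp(-outer(k^2, k^2, `+`) / (2 * 0.08^2))
  base <- Re(stats::fft(stats::fft(base) * lp, inverse = TRUE)) / length(base)
  base <- (base - min(base)) / (max(base) - min(base))
  sig <- stats::sd(base)
  worst <- 0
  for (i in 1:50) {
    d <- stats::runif(2, -2, 2)
    mov <- fourier_shift(base, d) +
      matrix(stats::rnorm(96 * 96, sd = sig / 10), 96, 96)
    fixed <- base + matrix(stats::rnorm(96 * 96, sd = sig / 10), 96, 96)
    sh <- phase_correlation_shift(fixed, mov, max_shift = 3)
    worst <- max(worst, max(abs(sh - d)))
  }
  expect_lt(worst, 0.1)
})
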