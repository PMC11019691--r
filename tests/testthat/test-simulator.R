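# Forward model: rendering, frame composition, acquisition sequencing and
# the timing model.

test_that("acquisition timing reproduces the instrument's rates", {
  r1 <- acquisition_time_ms(acquisition_timing(exposure_ms = 1))
  expect_equal(r1$rate_hz, 7.0)
  r20 <- acquisition_time_ms(acquisition_timing(exposure_ms = 20))
  expect_equal(r20$time_ms_rounded, 428)
  expect_equal(r20$rate_hz, 2.3)
  r0 <- acquisition_time_ms(acquisition_timing(exposure_ms = 0))
  expect_equal(r0$time_ms, 127.5)
  # z-stepping adds one piezo translation per step; none without stepping
  rz <- acquisition_time_ms(acquisition_timing(exposure_ms = 20, n_zsteps = 2))
  expect_equal(rz$time_ms, 2 * 15 * 28.5 + 2 * 170)
  expect_error(acquisition_time_ms(
    acquisition_timing(exposure_ms = 0, readout_ms = 0)), "degenerate")
})

test_that("plane rendering is linear and reproduces the PSF for a point", {
  cfg <- small_cfg()
  px <- cfg$px_sample
  psf <- generate_psf(cfg, shape = c(65, 65), voxel = c(z = 1, y = px, x = px),
                      z_offsets = c(-264, 0, 264))
  zero <- density_phantom(array(0, c(65, 65, 1)), c(z = 264, y = px, x = px))
  expect_equal(max(abs(render_plane_image(zero, psf, NULL, 0))), 0)

  delta <- array(0, c(65, 65, 1)); delta[33, 33, 1] <- 500
  ph <- density_phantom(delta, c(z = 264, y = px, x = px))
  img <- render_plane_image(ph, psf, NULL, 0)
  expect_equal(img, 500 * psf$data[, , 2], tolerance = 1e-12)

  ph2 <- ph; ph2$volume <- 2 * ph2$volume
  expect_equal(render_plane_image(ph2, psf, NULL, 0), 2 * img,
               tolerance = 1e-12)
  expect_error(render_plane_image(ph, psf, NULL, 100), "resample")
})

test_that("frame composition keeps exact photon bookkeeping when noiseless", {
  mf <- multifocus_config(tile_px = 8, frame_px = 36, dz = 264)
  cam <- camera_config(frame_px = 36, gain = 1, offset = 100, read_noise = 0)
  zeros <- lapply(1:7, function(i) matrix(0, 8, 8))
  fr <- compose_camera_frame(zeros, mf, cam, noise = FALSE)
  expect_true(all(fr == 100))

  imgs <- lapply(1:7, function(i) matrix(stats::runif(64) * 50, 8, 8))
  fr2 <- compose_camera_frame(imgs, mf, cam, noise = FALSE)
  expect_equal(sum(fr2 - 100),
               sum(sapply(1:7, function(p) 0.11 * sum(imgs[[p]]))),
               tolerance = 1e-9)

  mf_bad <- mf; mf_bad$jitter[1, ] <- c(50L, 0L)
  expect_error(compose_camera_frame(imgs, mf_bad, cam, noise = FALSE),
               "layout")
})

test_that("camera noise matches Poisson + read-noise statistics", {
  mf <- multifocus_config(tile_px = 8, frame_px = 36)
  cam <- camera_config(frame_px = 36, gain = 1, offset = 10, read_noise = 2)
  imgs <- lapply(1:7, function(i) matrix(40 / 0.11, 8, 8))  # 40 expected photons
  n <- 2500
  vals <- vapply(seq_len(n), function(s) {
    compose_camera_frame(imgs, mf, cam, seed = s)[5, 5]
  }, numeric(1))
  mu <- mean(vals) - 10
  se <- sqrt(40 + 4) / sqrt(n)
  expect_lt(abs(mu - 40), 3 * se + 0.05)            # 0.05 allows ADC rounding bias
  expect_lt(abs(stats::var(vals) - (40 + 4)) / 44, 0.12)
})

test_that("acquisitions have the right frame count, order and determinism", {
  fx <- filament_fixture()
  expect_equal(dim(fx$raw$frames)[3], 15)
  expect_equal(fx$raw$index$phase[1:6], c(1:5, 1))

  pat2 <- illumination_pattern(beam_mode = "two_beam")
  raw2 <- simulate_acquisition(fx$ph, pat2, fx$cfg, fx$mf, fx$cam,
                               noise = FALSE, seed = 1)
  expect_equal(dim(raw2$frames)[3], 9)

  # same seed, bit-identical output (with noise)
  cam <- camera_config(frame_px = 320)
  ra <- simulate_acquisition(fx$ph, fx$pat, fx$cfg, fx$mf, cam, seed = 42)
  rb <- simulate_acquisition(fx$ph, fx$pat, fx$cfg, fx$mf, cam, seed = 42)
  expect_identical(ra$frames, rb$frames)
})

test_that("interleaved z-stepping books 132 nm offsets for every frame", {
  cfg <- small_cfg(); px <- cfg$px_sample
  ph <- density_phantom(array(1, c(24, 24, 1)), c(z = 264, y = px, x = px))
  mf <- multifocus_config(tile_px = 24, frame_px = 100)
  cam <- camera_config(frame_px = 100, gain = 1, offset = 0, read_noise = 0)
  tim <- acquisition_timing(exposure_ms = 20, n_zsteps = 2, zstep_nm = 132)
  raw <- simulate_acquisition(ph, illumination_pattern(), cfg, mf, cam, tim,
                              timepoints = 2, noise = FALSE, seed = 1)
  expect_equal(dim(raw$frames)[3], 60)
  gt <- raw$ground_truth$plane_z
  s1 <- raw$index$zstep == 1
  expect_true(all(gt[s1, ] == rep(mf$z_offsets, each = sum(s1))))
  expect_true(all(gt[!s1, ] == rep(mf$z_offsets + 132, each = sum(!s1))))
})

test_that("phase averaging equals uniform illumination of the same mean power", {
  fx <- filament_fixture()
  raw <- fx$raw
  map <- fx$map
  # average the 5 phase frames of orientation 1 and compare with the
  # widefield simulation (uniform illumination at the pattern's mean)
  wf_raw <- simulate_acquisition(fx$ph, fx$pat, fx$cfg, fx$mf, fx$cam,
                                 noise = FALSE, seed = 1, widefield = TRUE)
  for (o in 1:2) {
    avg <- matrix(0, 320, 320)
    for (j in 1:5) {
      fr <- raw$index$frame[raw$index$orientation == o & raw$index$phase == j]
      avg <- avg + raw$frames[, , fr] / 5
    }
    expect_lt(max(abs(avg - wf_raw$frames[, , 1])) / max(wf_raw$frames[, , 1]),
              1e-9)
  }
})

test_that("the efficiency vector is conserved through noiseless composition", {
  fx <- filament_fixture()
  # direct render of plane 4 under orientation 1 / phase 1 illumination
  raw <- fx$raw
  tiles <- extract_planes(raw$frames[, , 1], fx$map)
  tp <- fx$mf$tile_px
  px <- fx$cfg$px_sample
  # the same defocus set (and hence PSF normalization) the simulator used
  defoci <- sort(unique(round(as.vector(
    outer(fx$ph$z_coords, fx$mf$z_offsets, `-`)), 6)))
  psf <- generate_psf(fx$cfg, shape = c(tp, tp),
                      voxel = c(z = 1, y = px, x = px), z_offsets = defoci)
  il <- illumination_field(fx$pat, fx$cfg, 1, 1, z = fx$ph$z_coords[1],
                           grid = c(tp, tp), px = px)
  img <- render_plane_image(fx$ph, psf, il, fx$mf$z_offsets[4])
  expect_equal(tiles[, , 4], 0.11 * img, tolerance = 1e-12)
})
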