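# Generalized Wiener reconstruction, widefield averaging and deconvolution.

test_that("wiener combination reduces to the identity in the trivial limit", {
  set.seed(2)
  img <- matrix(stats::runif(48 * 48), 48, 48)
  bands <- structure(list(orders = 0L,
                          spectra = list("0" = stats::fft(img))),
                     class = "band_set")
  est <- structure(list(wave_vector = c(0, 0.004), k1 = c(0, 0.004),
                        angle_deg = 0, period_nm = 250, phase = 0,
                        m1 = 1, m2 = NA_real_, orientation_idx = 1),
                   class = "pattern_estimate")
  cfg <- small_cfg()
  out <- wiener_combine(bands, est, cfg, illumination_pattern(),
                        w = 1e-6, upsample = 1, apod = "none",
                        notch = list(depth = 0), otf = function(k) rep(1, length(k)))
  expect_equal(unclass(out), img, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_lt(attr(out, "imag_residual"), 1e-9)
  expect_error(wiener_combine(bands, est, cfg, illumination_pattern(), w = 0),
               "w must be positive")
})

test_that("reconstructed bead spectra extend the widefield support ~1.74x", {
  fx <- bead_fixture()
  # radially averaged spectral amplitude; support at the 1e-3 threshold
  # (the same magnitude convention used for the OTF support). The plane
  # is recombined without the nonnegativity clamp, whose harmonics would
  # otherwise contaminate the spectrum above the cutoff.
  sup <- function(img, pxs) {
    S <- Mod(stats::fft(img))
    S[1, 1] <- 0
    k <- fft_freq(nrow(img), pxs)
    km <- sqrt(outer(k^2, k^2, `+`))
    dk <- 1 / (nrow(img) * pxs)
    bin <- pmin(floor(km / dk) + 1, 200)
    prof <- tapply(as.vector(S), as.vector(bin), mean)
    th <- 1e-3 * max(prof)
    max(as.numeric(names(prof)[prof > th])) * dk
  }
  bands_list <- list(); est_list <- list()
  for (o in 1:3) {
    bands_list[[o]] <- separate_bands(orientation_tiles(fx$raw, fx$map, o, 4))
    est_list[[o]] <- estimate_pattern(bands_list[[o]], fx$pat, fx$cfg,
                                      orientation_idx = o)
  }
  plane <- wiener_combine(bands_list, est_list, fx$cfg, fx$pat, clamp = FALSE)
  s_wf <- sup(fx$wf$data[, , 4], fx$cfg$px_sample)
  s_sr <- sup(plane, fx$cfg$px_sample / 2)
  expect_lt(abs(s_sr / s_wf - 1.74), 0.1)
})

test_that("volumes assemble with the right plane spacing and interleaving", {
  fx <- bead_fixture()
  expect_equal(length(fx$recon$z_coords), 7)
  expect_equal(unique(diff(fx$recon$z_coords)), 264)
  expect_equal(dim(fx$recon$data)[1], 192)  # 2x lateral upsampling

  # interleaved two-step acquisition -> 14 planes at 132 nm
  cfg <- small_cfg(); px <- cfg$px_sample
  ph <- density_phantom(array(stats::runif(48 * 48) * 100, c(48, 48, 1)),
                        c(z = 264, y = px, x = px))
  mf <- multifocus_config(tile_px = 48, frame_px = 170)
  cam <- camera_config(frame_px = 170, gain = 1, offset = 0, read_noise = 0)
  tim <- acquisition_timing(exposure_ms = 20, n_zsteps = 2, zstep_nm = 132)
  raw <- simulate_acquisition(ph, illumination_pattern(), cfg, mf, cam, tim,
                              noise = FALSE, seed = 2)
  map <- calibrate_tile_map(raw, mf)
  rec <- suppressWarnings(reconstruct_volume(raw, map, estimate = FALSE,
                                             align = FALSE))
  expect_equal(length(rec$z_coords), 14)
  expect_true(all(diff(rec$z_coords) == 132))
  expect_true(all(diff(rec$z_coords) > 0))
})

test_that("reconstruction of a uniform phantom is flat and linear in density", {
  cfg <- small_cfg(); px <- cfg$px_sample
  ph <- density_phantom(array(200, c(48, 48, 1)), c(z = 264, y = px, x = px))
  mf <- multifocus_config(tile_px = 48, frame_px = 170)
  cam <- camera_config(frame_px = 170, gain = 1, offset = 0, read_noise = 0)
  raw <- simulate_acquisition(ph, illumination_pattern(), cfg, mf, cam,
                              noise = FALSE, seed = 2)
  map <- calibrate_tile_map(raw, mf)
  # a uniform sample has no pattern-estimation features; nominal parameters
  rec <- suppressWarnings(reconstruct_volume(raw, map, estimate = FALSE,
                                             align = FALSE))
  # away from the tile-border apron (the pattern is not periodic over the
  # tile, so a Gibbs fringe hugs the edges)
  mid <- rec$data[25:72, 25:72, 4]
  expect_lt(stats::sd(mid) / mean(mid), 0.01)

  ph2 <- ph; ph2$volume <- ph2$volume * 3
  raw2 <- simulate_acquisition(ph2, illumination_pattern(), cfg, mf, cam,
                               noise = FALSE, seed = 2)
  rec2 <- suppressWarnings(reconstruct_volume(raw2, map, estimate = FALSE,
                                              align = FALSE))
  expect_equal(unclass(rec2$data[, , 4]), unclass(3 * rec$data[, , 4]),
               tolerance = 0.01, ignore_attr = TRUE)
})

test_that("widefield averaging cancels the stripes and conserves the mean", {
  fx <- filament_fixture()
  wf <- widefield_average(fx$raw, fx$map)
  expect_equal(dim(wf$data), c(96, 96, 7))
  # oracle: plain mean over the extracted plane stacks
  acc <- matrix(0, 96, 96)
  for (f in fx$raw$index$frame)
    acc <- acc + extract_planes(fx$raw$frames[, , f], fx$map)[, , 4] / 15
  expect_equal(wf$data[, , 4], acc, tolerance = 1e-12)

  # constant frames -> constant volume
  raw_c <- fx$raw
  raw_c$frames[] <- 7.5
  wf_c <- widefield_average(raw_c, fx$map)
  expect_true(all(wf_c$data == 7.5))

  # stripes cancel over full phase cycles: widefield of a uniform phantom
  cfg <- small_cfg(); px <- cfg$px_sample
  ph <- density_phantom(array(100, c(48, 48, 1)), c(z = 264, y = px, x = px))
  mf <- multifocus_config(tile_px = 48, frame_px = 170)
  cam <- camera_config(frame_px = 170, gain = 1, offset = 0, read_noise = 0)
  raw_u <- simulate_acquisition(ph, illumination_pattern(), cfg, mf, cam,
                                noise = FALSE, seed = 3)
  map_u <- calibrate_tile_map(raw_u, mf)
  wf_u <- widefield_average(raw_u, map_u)
  mid <- wf_u$data[5:44, 5:44, 4]
  expect_lt((max(mid) - min(mid)) / mean(mid), 1e-9)

  raw_bad <- fx$raw
  raw_bad$frames <- raw_bad$frames[, , 1:14]
  raw_bad$index <- raw_bad$index[1:14, ]
  expect_error(widefield_average(raw_bad, fx$map), "incomplete")
})

test_that("Richardson-Lucy conserves flux and sharpens a blurred bead", {
  cfg <- small_cfg(); px <- cfg$px_sample
  psf <- generate_psf(cfg, shape = c(49, 49), voxel = c(z = 1, y = px, x = px),
                      z_offsets = 0)
  delta_k <- array(0, c(49, 49, 1)); delta_k[25, 25, 1] <- 1

  img <- array(0, c(49, 49, 1)); img[25, 25, 1] <- 900
  blurred <- array(Re(stats::fft(stats::fft(img[, , 1]) *
                                 stats::fft(ifftshift(psf$data[, , 1])),
                                 inverse = TRUE)) / 49^2, c(49, 49, 1))

  expect_equal(rl_deconvolve(blurred, delta_k, iterations = 5), blurred,
               tolerance = 1e-9)

  dec <- rl_deconvolve(blurred, psf, iterations = 20)
  expect_lt(abs(sum(dec) - sum(blurred)) / sum(blurred), 0.005)
  fw_b <- measure_fwhm(blurred, matrix(c(24 * px, 24 * px, 0), 1),
                       voxel = c(z = 1, y = px, x = px))
  fw_d <- measure_fwhm(dec, matrix(c(24 * px, 24 * px, 0), 1),
                       voxel = c(z = 1, y = px, x = px))
  expect_lt(fw_d$mean["x"], fw_b$mean["x"])
  expect_warning(rl_deconvolve(blurred - 1, psf, iterations = 1), "clamped")
})

test_that("lateral resolution improves ~2x while axial FWHM is unchanged", {
  fx <- bead_fixture()
  pos <- fx$em$positions
  pos[, 3] <- 0
  fw_wf <- measure_fwhm(fx$wf, pos)
  fw_sr <- measure_fwhm(fx$recon, pos)
  lat_ratio <- mean(fw_sr$mean[c("x", "y")]) / mean(fw_wf$mean[c("x", "y")])
  ax_ratio <- fw_sr$mean["z"] / fw_wf$mean["z"]
  expect_lte(lat_ratio, 0.65)
  expect_gte(ax_ratio, 0.85)
  expect_lte(ax_ratio, 1.1)
})

test_that("three-beam reconstruction sections better than two-beam than widefield", {
  sx <- sheets_fixture()
  iz_in <- which.min(abs(sx$three_beam$z_coords - 0))
  iz_out <- which.min(abs(sx$three_beam$z_coords - 800))
  c3 <- axial_contrast(sx$three_beam, iz_in, iz_out)
  c2 <- axial_contrast(sx$two_beam, iz_in, iz_out)
  cw <- axial_contrast(sx$wf, which.min(abs(sx$wf$z_coords - 0)),
                       which.min(abs(sx$wf$z_coords - 800)))
  expect_gte(c3 - c2, 0.05)
  expect_gte(c2 - cw, 0.05)
})
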