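test_that("the fringe centre is recovered to subpixel accuracy", {
  fx <- cap12()
  ctr <- find_fringe_center(fx$image)
  expect_lt(max(abs(ctr - fx$center_px)), 0.5)
})

test_that("centre finding is translation-equivariant", {
  base <- cap_fixture(n_antinodes = 8, image_size = 256)
  moved <- cap_fixture(n_antinodes = 8, image_size = 256,
                       center_offset_px = c(10, -7))
  c0 <- find_fringe_center(base$image)
  c1 <- find_fringe_center(moved$image)
  expect_equal(c1 - c0, c(x = 10, y = -7), tolerance = 0.5)
})

test_that("a structureless image raises centre-not-found", {
  flat <- fringe_image(matrix(7, 64, 64), 100)
  expect_error(find_fringe_center(flat), class = "swf_centre_not_found")
  set.seed(11)
  noise <- fringe_image(matrix(rnorm(64^2, 100, 1), 64, 64), 100)
  expect_error(find_fringe_center(noise), class = "swf_centre_not_found")
})

test_that("radial profile averages annuli and drops empty bins", {
  img <- fringe_image(matrix(3.5, 64, 64), 100)
  prof <- radial_profile(img, center_px = c(32, 32))
  expect_true(all(abs(prof$intensity - 3.5) < 1e-12))
  expect_true(all(diff(prof$radius_nm) > 0))
  # doubling the bin width halves the bin count (+/- 1)
  prof2 <- radial_profile(img, center_px = c(32, 32), bin_width_nm = 200)
  expect_lt(abs(length(prof2$radius_nm) - length(prof$radius_nm) / 2), 2)
  expect_error(radial_profile(img, center_px = c(32, 32), bin_width_nm = 10),
               class = "swf_config_error")
})

test_that("noiseless cap profile peaks at the predicted antinode radii", {
  fx <- cap12()
  prof <- radial_profile(fx$image, center_px = fx$center_px)
  pk <- detect_peaks(prof)
  pred <- cap_antinode_radii(fx$spec, fx$cfg)
  expect_equal(nrow(pk), length(pred))
  expect_lt(max(abs(pk$radius_nm - pred)), fx$pixel_size_nm)
})

test_that("single-ray profile agrees with the azimuthal mean on symmetric scenes", {
  fx <- cap12()
  az <- radial_profile(fx$image, center_px = fx$center_px)
  ray <- radial_profile(fx$image, center_px = fx$center_px, method = "ray",
                        ray_angle = pi / 5)
  common <- intersect(az$radius_nm, ray$radius_nm)
  common <- common[common > 10 * fx$pixel_size_nm &
                   common < 200 * fx$pixel_size_nm]
  a <- az$intensity[match(common, az$radius_nm)]
  b <- ray$intensity[match(common, ray$radius_nm)]
  expect_gt(cor(a, b), 0.98)
})

test_that("detect_peaks locates analytic sin^2 maxima", {
  r <- seq(1, 600, by = 1)
  prof <- make_profile(r, sin(pi * r / 100)^2)
  pk <- detect_peaks(prof)
  expect_equal(pk$radius_nm, c(50, 150, 250, 350, 450, 550),
               tolerance = 0.5 / 50)
  expect_error(detect_peaks(make_profile(r, r * 0.001)),
               class = "swf_no_peaks")
})

test_that("refined peaks match a 100x oversampled brute-force argmax", {
  set.seed(7)
  for (case in 1:50) {
    x <- seq(0, 100, by = 1)
    f1 <- runif(1, 0.05, 0.12); f2 <- runif(1, 0.01, 0.03)
    y <- 1 + sin(2 * pi * f1 * x + runif(1, 0, 2 * pi)) +
      0.5 * sin(2 * pi * f2 * x + runif(1, 0, 2 * pi))
    prof <- make_profile(x + 0.5, y)
    pk <- tryCatch(detect_peaks(prof, min_prominence = 0.2),
                   swf_no_peaks = function(e) NULL)
    if (is.null(pk)) next
    spl <- splinefun(prof$radius_nm, prof$intensity, method = "fmm")
    for (r0 in pk$radius_nm) {
      i <- which.min(abs(prof$radius_nm - r0))
      lo <- prof$radius_nm[max(i - 1, 1)]
      hi <- prof$radius_nm[min(i + 1, length(x))]
      grid <- seq(lo, hi, length.out = 100 * 2 + 1)
      brute <- grid[which.max(spl(grid))]
      expect_lt(abs(r0 - brute), 0.1)
    }
  }
})

test_that("radii map to a 257 nm antinode ladder", {
  cfg <- optics_config(514)
  spec <- spherical_cap(30, max_field_radius_um = 700)
  r_k <- cap_antinode_radii(spec, cfg)
  pk <- structure(data.frame(radius_nm = r_k, amplitude = 1),
                  class = c("fringe_peaks", "data.frame"))
  pk <- radii_to_heights(pk, spec, cfg)
  expect_equal(pk$z_nm, (2 * pk$antinode_index + 1) * 128.5,
               tolerance = 1e-9)
  est <- estimate_spacing(pk)
  expect_equal(est$spacing_nm, 257, tolerance = 1e-9)
  expect_lt(est$sd_nm, 1e-6)
  bad <- structure(data.frame(radius_nm = 31e6, amplitude = 1),
                   class = c("fringe_peaks", "data.frame"))
  expect_error(radii_to_heights(bad, spec), class = "swf_analysis_error")
  expect_error(estimate_spacing(pk[1:2, ]), class = "swf_analysis_error")
})

test_that("relative spacing error reproduces the benchmark arithmetic", {
  cfg <- optics_config(514)
  expect_equal(round(spacing_relative_error(255, cfg), 2), 0.78)
  expect_equal(spacing_relative_error(257, cfg), 0)
})

test_that("spacing estimate is invariant to intensity scaling", {
  fx <- cap_fixture(n_antinodes = 10, image_size = 256, photon_scale = 500,
                    background = 5, seed = 3)
  rep1 <- analyze_fringe_image(fx$image, fx$spec, fx$cfg)
  scaled <- fringe_image(fx$image$data * 7.3, fx$image$pixel_size_nm)
  rep2 <- analyze_fringe_image(scaled, fx$spec, fx$cfg,
                               center_px = rep1$center_px)
  expect_equal(rep2$spacing_nm, rep1$spacing_nm, tolerance = 1e-9)
})

test_that("a constructed beat envelope yields L = 4517 nm", {
  z <- seq(128.5, 7100, by = 257)
  pk <- structure(data.frame(radius_nm = z, amplitude =
                               sin(pi * z / 2258.5)^2, z_nm = z,
                             antinode_index = seq_along(z) - 1L),
                  class = c("fringe_peaks", "data.frame"))
  est <- estimate_envelope_period(pk, n = 1)
  expect_equal(est$L_nm, 4517, tolerance = 0.01)
  # unmodulated amplitudes: no envelope
  pk$amplitude <- 1 + 1e-6 * cos(seq_along(z))
  expect_error(estimate_envelope_period(pk, n = 1),
               class = "swf_no_envelope")
})

test_that("the moire envelope phase ranks the true base index first", {
  cfg <- optics_config(514, 580, 5, mode = "narrowband_moire")
  L <- moire_period(514, 580)
  for (b_true in c(0L, 2L, 4L)) {
    idx <- 0:25
    z <- (2 * (idx + b_true) + 1) * 128.5
    pk <- structure(data.frame(radius_nm = z, amplitude =
                                 cos(2 * pi * z / L)^2, z_nm = z,
                               antinode_index = idx),
                    class = c("fringe_peaks", "data.frame"))
    rk <- rank_base_index(pk, cfg, candidates = 0:6)
    expect_equal(rk$base_index[1], b_true)
  }
})

test_that("spacing recovery holds across 20 seeded noisy fixtures", {
  spacings <- vapply(1:20, function(s) {
    fx <- cap_fixture(n_antinodes = 10, image_size = 256,
                      photon_scale = 500, background = 5, seed = s)
    analyze_fringe_image(fx$image, fx$spec, fx$cfg)$spacing_nm
  }, numeric(1))
  expect_lt(abs(mean(spacings) - 257) / 257, 0.01)
  expect_true(all(abs(spacings - 257) / 257 < 0.02))
})

test_that("envelope recovery holds on independently seeded moire fixtures", {
  for (s in 1:2) {
    fx <- cap_fixture(n_antinodes = 28, image_size = 512,
                      mode = "narrowband_moire", photon_scale = 500,
                      background = 5, seed = 100 + s)
    rep <- analyze_fringe_image(fx$image, fx$spec, fx$cfg, envelope = TRUE)
    expect_lt(abs(rep$envelope_L_nm - 4517) / 4517, 0.05)
  }
})
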