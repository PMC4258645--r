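test_that("flat surface at the first antinode renders uniformly bright", {
  cfg <- optics_config(514)
  hm <- height_map(matrix(514 / 4, 64, 64), 100)
  img <- render_monolayer_image(hm, cfg)
  expect_equal(img$data, matrix(1, 64, 64))
})

test_that("renders are bit-identical for a fixed seed", {
  fx1 <- cap_fixture(n_antinodes = 8, image_size = 128, photon_scale = 200,
                     background = 5, read_noise_sd = 2, seed = 42)
  fx2 <- cap_fixture(n_antinodes = 8, image_size = 128, photon_scale = 200,
                     background = 5, read_noise_sd = 2, seed = 42)
  expect_identical(fx1$image$data, fx2$image$data)
  fx3 <- cap_fixture(n_antinodes = 8, image_size = 128, photon_scale = 200,
                     background = 5, read_noise_sd = 2, seed = 43)
  expect_false(identical(fx1$image$data, fx3$image$data))
})

test_that("the specimen-mirror contact point is dark", {
  fx <- cap_fixture(n_antinodes = 8, image_size = 128)
  ctr <- round(fx$center_px)
  expect_lt(fx$image$data[ctr[2], ctr[1]], 1e-3)
})

test_that("noisy renders average to the noiseless field", {
  fx0 <- cap_fixture(n_antinodes = 6, image_size = 96)
  scale <- 100; N <- 30
  acc <- 0
  for (s in seq_len(N))
    acc <- acc + cap_fixture(n_antinodes = 6, image_size = 96,
                             photon_scale = scale, seed = s)$image$data
  mean_img <- acc / N
  bright <- fx0$image$data > 0.5
  rel_err <- abs(mean_img[bright] / scale - fx0$image$data[bright]) /
    fx0$image$data[bright]
  expect_lt(mean(rel_err), 3 / sqrt(N * scale))
})

test_that("noiseless cap renders are azimuthally symmetric", {
  img <- cap12()$image$data
  # exact-radius groups about the (inter-pixel) centre share one intensity
  n <- nrow(img)
  idx <- which(matrix(TRUE, n, n), arr.ind = TRUE)
  r2 <- (idx[, 1] - n / 2 - 0.5)^2 + (idx[, 2] - n / 2 - 0.5)^2
  sub <- r2 < (n / 2 - 4)^2
  cv <- tapply(img[sub], r2[sub], function(v)
    if (mean(v) > 1e-6) sd(v) / mean(v) else 0)
  expect_lt(max(cv, na.rm = TRUE), 1e-6)
})

test_that("membrane render sums two sheets with foreshortening", {
  cfg <- optics_config(488, refractive_index = 1.34)
  z <- matrix(300, 64, 64)
  one <- render_membrane_image(height_map(z, 100), height_map(z, 100), cfg)
  # degenerate shell: both sheets coincide, so the signal doubles
  single <- detected_intensity(300, cfg)
  expect_equal(one$data[20:40, 20:40],
               matrix(2 * single, 21, 21), tolerance = 1e-9)
  bad <- height_map(z + 10, 100)
  expect_error(render_membrane_image(height_map(z, 100), bad, cfg),
               class = "swf_config_error")
})

test_that("plain-slide control shows only the bright cell outline", {
  fx <- discocyte_fixture(image_size = 192, mirror_present = FALSE)
  ctr <- c(96, 96)
  prof <- radial_profile(fx$image, center_px = ctr)
  rho <- prof$radius_nm / (fx$spec$diameter_nm / 2)
  centre <- mean(prof$intensity[rho < 0.15])
  rim <- max(prof$intensity[rho > 0.7 & rho < 1.05])
  expect_gt(rim / centre, 3)
})

test_that("membrane fringe peaks sit where the sheets cross antinodes", {
  fx <- discocyte_fixture(image_size = 256)
  cfg <- fx$cfg; spec <- fx$spec
  half <- axial_fwhm(cfg)
  # analytic crossing radii of both sheets with every antinodal plane
  rho <- seq(0, 1, length.out = 8001)
  mid <- spec$rim_thickness_nm / 2
  Tt <- discocyte_thickness(rho, spec)
  crossings <- c()
  for (sheet in list(mid + Tt / 2, mid - Tt / 2)) {
    zmax <- max(sheet)
    ks <- 0:floor((zmax / half - 1) / 2)
    for (k in ks) {
      zk <- (2 * k + 1) * half
      s <- sheet - zk
      hit <- which(s[-1] * s[-length(s)] <= 0)
      crossings <- c(crossings, rho[hit] * spec$diameter_nm / 2)
    }
  }
  prof <- radial_profile(fx$image, center_px = c(128, 128))
  pk <- detect_peaks(prof, min_prominence = 0.1)
  # every detected fringe must be near an analytic crossing; the
  # foreshortening weighting can pull a rendered peak a few pixels off
  # the geometric crossing, so the match tolerance is 4 px
  ps <- fx$pixel_size_nm
  for (r in pk$radius_nm)
    expect_lt(min(abs(crossings - r)), 4 * ps)
  expect_gt(nrow(pk), 4)
})

test_that("subtraction pair cancels for a vanishing Stokes shift", {
  surface <- cap12()$surface
  pair <- simulate_subtraction_pair(surface, 514, 514.5, 1,
                                    detection_bandwidth_nm = 0)
  expect_lt(max(pair$difference$data), 0.05)
  ctr <- round(cap12()$center_px)
  # both patterns share the node at the mirror: difference dark at contact
  pair2 <- simulate_subtraction_pair(surface, 514, 580, 1)
  expect_lt(pair2$difference$data[ctr[2], ctr[1]], 1e-3)
  expect_error(simulate_subtraction_pair(surface, 580, 514, 1),
               class = "swf_config_error")
})

test_that("clipped subtraction is anti-symmetric", {
  fx <- cap_fixture(n_antinodes = 6, image_size = 96, photon_scale = 100,
                    seed = 1)
  fy <- cap_fixture(n_antinodes = 6, image_size = 96, photon_scale = 100,
                    seed = 2)
  ab <- subtract_images(fx$image, fy$image)
  ba <- subtract_images(fy$image, fx$image)
  expect_equal(ab$data + ba$data, abs(fx$image$data - fy$image$data))
  expect_equal(subtract_images(fx$image, fx$image)$data,
               matrix(0, 96, 96))
  small <- fringe_image(matrix(0, 32, 32), fx$image$pixel_size_nm)
  expect_error(subtract_images(fx$image, small), class = "swf_config_error")
})

test_that("negative blur is rejected and blur smooths the field", {
  fx <- cap12()
  expect_error(render_monolayer_image(fx$surface, fx$cfg,
                                      blur_sigma_nm = -1),
               class = "swf_config_error")
  blurred <- render_monolayer_image(fx$surface, fx$cfg,
                                    blur_sigma_nm = 2 * fx$pixel_size_nm)
  expect_lt(sd(blurred$data), sd(fx$image$data))
})
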