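# Shared synthetic scenes, built once per test run. All fixtures are
# generated in code; the heavier ones are cached so several test files can
# reuse the same render.

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, expr, envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# Noiseless 12-ring calibration cap (514 nm, air), 512 px.
cap12 <- function() cached_fixture("cap12",
  cap_fixture(n_antinodes = 12, image_size = 512))

# Noisy 22-ring cap: the standard spacing-recovery scene.
cap22_noisy <- function() cached_fixture("cap22_noisy",
  cap_fixture(n_antinodes = 22, image_size = 512, photon_scale = 500,
              background = 5, seed = 0))

# Narrowband moire cap spanning just over 3 beat periods in height.
moire28_noisy <- function() cached_fixture("moire28_noisy",
  cap_fixture(n_antinodes = 28, image_size = 512,
              mode = "narrowband_moire", detection_center_nm = 580,
              detection_bandwidth_nm = 5, photon_scale = 500,
              background = 5, seed = 0))

# Hand-built radial profile object (bypasses image rendering).
make_profile <- function(radius_nm, intensity, bin_width_nm = 1) {
  structure(list(radius_nm = radius_nm, intensity = intensity,
                 bin_width_nm = bin_width_nm, center_px = c(0, 0)),
            class = "radial_profile")
}

# Hand-built contour set: concentric circles of given radii (nm).
make_circle_contours <- function(radii_nm, center_nm = c(0, 0),
                                 n_pts = 90, pixel_size_nm = 100,
                                 dims = NULL) {
  th <- seq(0, 2 * pi, length.out = n_pts + 1)[-1]
  contours <- lapply(radii_nm, function(r)
    list(xy = cbind(x = center_nm[1] + r * cos(th),
                    y = center_nm[2] + r * sin(th)),
         strength = 1, antinode_index = NA_integer_, z_nm = NA_real_))
  structure(contours, class = "contour_set",
            pixel_size_nm = pixel_size_nm, dims = dims)
}
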