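#' Synthetic spherical-cap fringe fixture
#'
#' One-call generator for the calibration scenes used throughout: a dyed
#' spherical cap on the mirror, imaged in a chosen detection mode. The
#' field of view is sized so the cap height at the field edge equals
#' `n_antinodes * lambda/2n` — i.e. exactly `n_antinodes` antinodal planes
#' intersect the surface, and the edge itself is a node.
#'
#' @param n_antinodes Number of antinodes spanned by the field.
#' @param image_size Raster side length in pixels (square image).
#' @param excitation_nm Excitation wavelength (nm).
#' @param refractive_index Medium index.
#' @param mode Detection mode (see [optics_config()]).
#' @param detection_center_nm,detection_bandwidth_nm Detection band for the
#'   narrowband / emission-only modes.
#' @param radius_mm Cap radius of curvature (mm).
#' @param photon_scale Expected counts at unit intensity, or NULL for a
#'   noiseless render.
#' @param background Background counts (inside the Poisson rate).
#' @param read_noise_sd Gaussian read noise (counts).
#' @param seed RNG seed for the noisy render.
#' @param blur_sigma_nm Lateral blur sigma (nm).
#' @param center_offset_px Optional `c(dx, dy)` displacement of the contact
#'   point from the image centre, in pixels.
#' @return A list with elements `image` ([fringe_image()]), `surface`
#'   ([height_map()]), `spec` ([spherical_cap()]), `cfg` ([optics_config()]),
#'   `center_px` (true fringe centre, pixel units) and `pixel_size_nm`.
#' @export
cap_fixture <- function(n_antinodes = 22, image_size = 512,
                        excitation_nm = 514, refractive_index = 1,
                        mode = "broadband_excitation_only",
                        detection_center_nm = 580,
                        detection_bandwidth_nm = 5,
                        radius_mm = 30, photon_scale = NULL,
                        background = 0, read_noise_sd = 0, seed = 0L,
                        blur_sigma_nm = 0, center_offset_px = c(0, 0)) {
  cfg <- optics_config(excitation_nm,
                       detection_center_nm =
                         if (mode == "broadband_excitation_only") NULL
                         else detection_center_nm,
                       detection_bandwidth_nm = detection_bandwidth_nm,
                       refractive_index = refractive_index, mode = mode)
  z_edge <- n_antinodes * antinode_spacing(cfg)
  R <- radius_mm * 1e6
  r_edge <- sqrt(2 * R * z_edge - z_edge^2)
  ps <- r_edge / (image_size / 2 - 1)
  center_px <- c(image_size / 2, image_size / 2) + center_offset_px
  spec <- spherical_cap(radius_mm,
                        contact_center_um = center_px * ps / 1e3,
                        max_field_radius_um = r_edge / 1e3)
  surface <- cap_height_map(spec, c(image_size, image_size), ps)
  noise <- if (!is.null(photon_scale))
    noise_model(photon_scale, read_noise_sd, background, seed)
  img <- render_monolayer_image(surface, cfg, noise, blur_sigma_nm)
  list(image = img, surface = surface, spec = spec, cfg = cfg,
       center_px = center_px, pixel_size_nm = ps)
}

#' Synthetic discocyte membrane fixture
#'
#' A membrane-stained red blood cell above the mirror (or on a plain slide
#' with `mirror_present = FALSE`), rendered from its upper and lower
#' membrane sheets.
#'
#' @param image_size Raster side length (pixels).
#' @param excitation_nm Excitation wavelength (nm); 488 with DiO staining
#'   in the motivating experiments.
#' @param refractive_index Mounting-medium index (1.34 for 4 % BSA in PBS).
#' @param diameter_um,center_thickness_um,rim_thickness_um,standoff_um,tilt
#'   Passed to [discocyte()].
#' @param mirror_present Standing-wave excitation on (mirror) or off
#'   (plain-slide control).
#' @param photon_scale,background,read_noise_sd,seed Noise settings, as in
#'   [cap_fixture()].
#' @param blur_sigma_nm Lateral blur sigma (nm).
#' @return A list with `image`, `upper`, `lower`, `spec`, `cfg`,
#'   `pixel_size_nm`.
#' @export
discocyte_fixture <- function(image_size = 256, excitation_nm = 488,
                              refractive_index = 1.34, diameter_um = 7.8,
                              center_thickness_um = 1.0,
                              rim_thickness_um = 2.5, standoff_um = 0,
                              tilt = c(0, 0), mirror_present = TRUE,
                              photon_scale = NULL, background = 0,
                              read_noise_sd = 0, seed = 0L,
                              blur_sigma_nm = 0) {
  cfg <- optics_config(excitation_nm, refractive_index = refractive_index)
  ps <- diameter_um * 1e3 * 1.3 / image_size   # 30 % margin around the cell
  ctr <- c(image_size / 2, image_size / 2) * ps / 1e3
  spec <- discocyte(diameter_um, center_thickness_um, rim_thickness_um,
                    standoff_um, center_um = ctr, tilt = tilt)
  sheets <- discocyte_surfaces(spec, c(image_size, image_size), ps)
  noise <- if (!is.null(photon_scale))
    noise_model(photon_scale, read_noise_sd, background, seed)
  img <- render_membrane_image(sheets$upper, sheets$lower, cfg, noise,
                               blur_sigma_nm, mirror_present)
  list(image = img, upper = sheets$upper, lower = sheets$lower,
       spec = spec, cfg = cfg, pixel_size_nm = ps)
}
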