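#' Detector noise model
#'
#' Photon shot noise plus additive Gaussian read noise: a pixel with
#' relative intensity I records
#' `Poisson(photon_scale * I + background) + Normal(0, read_noise_sd)`.
#'
#' @param photon_scale Expected counts at unit relative intensity, > 0.
#' @param read_noise_sd Read-noise standard deviation (counts), >= 0.
#' @param background Expected background counts (inside the Poisson rate).
#' @param seed Integer seed; renders are bit-reproducible given the seed.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(photon_scale = 500, read_noise_sd = 0,
                        background = 0, seed = 0L) {
  stopifnot_scalar_num(photon_scale, "photon_scale", 0, strict_min = TRUE)
  stopifnot_scalar_num(read_noise_sd, "read_noise_sd", 0)
  stopifnot_scalar_num(background, "background", 0)
  structure(list(photon_scale = photon_scale, read_noise_sd = read_noise_sd,
                 background = background, seed = as.integer(seed)),
            class = "noise_model")
}

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' 2D fringe image container
#'
#' @param data Numeric matrix of intensities (counts), >= 0.
#' @param pixel_size_nm Pixel size (nm), > 0.
#' @param metadata Named list of provenance (optics, specimen, noise, seed).
#' @return An object of class `fringe_image`.
#' @export
fringe_image <- function(data, pixel_size_nm, metadata = list()) {
  if (!is.matrix(data) || !is.numeric(data))
    swf_config_error("'data' must be a numeric matrix", field = "data")
  stopifnot_scalar_num(pixel_size_nm, "pixel_size_nm", 0, strict_min = TRUE)
  structure(list(data = data, pixel_size_nm = pixel_size_nm,
                 metadata = metadata),
            class = "fringe_image")
}

#' @export
print.fringe_image <- function(x, ...) {
  cat(sprintf("<fringe_image> %d x %d px @ %g nm/px, counts in [%g, %g]\n",
              nrow(x$data), ncol(x$data), x$pixel_size_nm,
              min(x$data), max(x$data)))
  invisible(x)
}

# Noiseless relative-intensity field -> counts, shared by the renderers.
apply_optics_noise <- function(field, pixel_size_nm, noise, blur_sigma_nm,
                               metadata) {
  if (blur_sigma_nm < 0)
    swf_config_error("blur_sigma_nm must be >= 0", field = "blur_sigma_nm")
  field[is.na(field)] <- 0
  if (blur_sigma_nm > 0)
    field <- as.matrix(EBImage::gblur(field, sigma = blur_sigma_nm / pixel_size_nm))
  if (is.null(noise)) {
    counts <- field                       # unit photon scale, noiseless
  } else {
    lambda <- noise$photon_scale * field + noise$background
    counts <- with_seed(noise$seed, {
      x <- stats::rpois(length(lambda), lambda)
      if (noise$read_noise_sd > 0)
        x <- x + stats::rnorm(length(lambda), 0, noise$read_noise_sd)
      x
    })
    counts <- matrix(pmax(counts, 0), nrow(field), ncol(field))
  }
  fringe_image(counts, pixel_size_nm, metadata)
}

#' Render a fluorescent-monolayer fringe image
#'
#' Simulates the concentric-fringe micrograph of a dyed surface above the
#' mirror: each pixel sees the standing-wave response
#' [detected_intensity()] at the local surface height, optionally blurred
#' laterally (a Gaussian standing in for the scanning PSF), then passed
#' through the [noise_model()]. Masked (NA) surface points contribute only
#' background; the contact point (z = 0) is dark, since the mirror is the
#' first node.
#'
#' @param surface A [height_map()].
#' @param cfg An [optics_config()].
#' @param noise A [noise_model()], or NULL for the noiseless relative field
#'   (unit photon scale, no background).
#' @param blur_sigma_nm Lateral Gaussian blur sigma (nm), >= 0 (0 = none).
#' @return A [fringe_image()] with full provenance metadata.
#' @export
render_monolayer_image <- function(surface, cfg, noise = NULL,
                                   blur_sigma_nm = 0) {
  stopifnot(inherits(surface, "height_map"))
  field <- detected_intensity(surface$z, cfg)
  apply_optics_noise(field, surface$pixel_size_nm, noise, blur_sigma_nm,
                     list(optics = unclass(cfg),
                          noise = if (!is.null(noise)) unclass(noise),
                          blur_sigma_nm = blur_sigma_nm,
                          kind = "monolayer"))
}

# Areal foreshortening of a dyed sheet: 1/cos(slope) = sqrt(1 + |grad z|^2),
# capped so near-vertical rims do not produce unbounded intensities.
foreshortening <- function(hm, max_factor = 20) {
  z <- hm$z; ps <- hm$pixel_size_nm
  gx <- z; gy <- z
  gx[] <- NA; gy[] <- NA
  nc <- ncol(z); nr <- nrow(z)
  gx[, 2:(nc - 1)] <- (z[, 3:nc] - z[, 1:(nc - 2)]) / (2 * ps)
  gy[2:(nr - 1), ] <- (z[3:nr, ] - z[1:(nr - 2), ]) / (2 * ps)
  f <- sqrt(1 + gx^2 + gy^2)
  f[is.na(f) & !is.na(z)] <- 1          # borders / mask edge
  pmin(f, max_factor)
}

#' Render a membrane-shell fringe image (two dyed sheets)
#'
#' Per-pixel signal is the sum over the upper and lower membrane sheets of
#' the standing-wave response at the sheet height, weighted by the areal
#' foreshortening `1/cos(slope)` of a uniformly dyed surface (steep rims
#' appear brighter). With `mirror_present = FALSE` the standing-wave factor
#' is replaced by a constant (cell on a plain slide): only the
#' foreshortening of the steep rim produces contrast, giving the familiar
#' bright cell outline.
#'
#' @param upper,lower [height_map()]s of the two sheets on a shared grid,
#'   with `upper >= lower` wherever both are defined.
#' @param cfg An [optics_config()].
#' @param noise A [noise_model()] or NULL.
#' @param blur_sigma_nm Lateral Gaussian blur sigma (nm).
#' @param mirror_present If FALSE, suppress the standing wave (control on a
#'   non-reflective slide).
#' @param foreshortening_max Cap on the foreshortening factor.
#' @return A [fringe_image()].
#' @export
render_membrane_image <- function(upper, lower, cfg, noise = NULL,
                                  blur_sigma_nm = 0, mirror_present = TRUE,
                                  foreshortening_max = 20) {
  stopifnot(inherits(upper, "height_map"), inherits(lower, "height_map"))
  if (!all(dim(upper$z) == dim(lower$z)) ||
      upper$pixel_size_nm != lower$pixel_size_nm)
    swf_config_error("upper and lower maps must share one grid",
                     field = "lower")
  if (any(upper$z < lower$z, na.rm = TRUE))
    swf_config_error("upper sheet must lie above lower sheet", field = "upper")
  sheet <- function(hm) {
    w <- foreshortening(hm, foreshortening_max)
    i <- if (mirror_present) detected_intensity(hm$z, cfg)
         else ifelse(is.na(hm$z), NA, 1)
    i * w
  }
  field <- sheet(upper)
  f2 <- sheet(lower)
  field[is.na(field)] <- 0; f2[is.na(f2)] <- 0
  apply_optics_noise(field + f2, upper$pixel_size_nm, noise, blur_sigma_nm,
                     list(optics = unclass(cfg),
                          noise = if (!is.null(noise)) unclass(noise),
                          mirror_present = mirror_present,
                          kind = "membrane"))
}

#' Excitation-only / emission-only image pair and their difference
#'
#' Renders the same surface twice — once with broadband detection (pure
#' excitation standing wave) and once with the excitation standing wave
#' suppressed (emission self-interference only, the notch-filter control) —
#' and returns both plus their pixel-wise difference clipped at zero. The
#' difference pattern beats at the same difference frequency as the directly
#' observed moire, with height period [moire_period()]`/2n`.
#'
#' @param surface A [height_map()].
#' @param excitation_nm,detection_nm Excitation / selected emission
#'   wavelengths (nm), `detection_nm > excitation_nm`.
#' @param refractive_index Medium index, >= 1.
#' @param noise A [noise_model()] or NULL. The two renders use seeds
#'   `seed` and `seed + 1` so their noise is independent.
#' @param detection_bandwidth_nm Detection band width (nm) for the
#'   emission-only render.
#' @return `list(excitation_only =, emission_only =, difference =)` of
#'   [fringe_image()]s.
#' @export
simulate_subtraction_pair <- function(surface, excitation_nm, detection_nm,
                                      refractive_index = 1, noise = NULL,
                                      detection_bandwidth_nm = 5) {
  if (detection_nm <= excitation_nm)
    swf_config_error("detection_nm must exceed excitation_nm",
                     field = "detection_nm")
  cfg_ex <- optics_config(excitation_nm, refractive_index = refractive_index,
                          mode = "broadband_excitation_only")
  cfg_em <- optics_config(excitation_nm, detection_center_nm = detection_nm,
                          detection_bandwidth_nm = detection_bandwidth_nm,
                          refractive_index = refractive_index,
                          mode = "emission_only")
  n2 <- noise
  if (!is.null(n2)) n2$seed <- n2$seed + 1L
  a <- render_monolayer_image(surface, cfg_ex, noise)
  b <- render_monolayer_image(surface, cfg_em, n2)
  list(excitation_only = a, emission_only = b,
       difference = subtract_images(a, b))
}
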