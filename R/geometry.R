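#' Gridded surface height above the mirror
#'
#' A rectangular raster of heights z(x, y) in nm above the mirror plane.
#' Pixel centres sit at physical coordinates `(j - 0.5) * pixel_size_nm`
#' (x, along columns) and `(i - 0.5) * pixel_size_nm` (y, along rows), with
#' the physical origin at the image corner. Points where the surface is
#' undefined (outside the specimen footprint) are NA.
#'
#' @param z Numeric matrix of heights (nm), all values >= 0 or NA.
#' @param pixel_size_nm Lateral size of one pixel (nm), > 0.
#' @return An object of class `height_map`.
#' @export
height_map <- function(z, pixel_size_nm) {
  if (!is.matrix(z) || !is.numeric(z))
    swf_config_error("'z' must be a numeric matrix", field = "z")
  stopifnot_scalar_num(pixel_size_nm, "pixel_size_nm", 0, strict_min = TRUE)
  if (any(z < 0, na.rm = TRUE))
    swf_config_error("heights must be >= 0 (above the mirror)", field = "z")
  structure(list(z = z, pixel_size_nm = pixel_size_nm),
            class = "height_map")
}

#' @export
print.height_map <- function(x, ...) {
  cat(sprintf("<height_map> %d x %d px @ %g nm/px, z in [%g, %g] nm (%d NA)\n",
              nrow(x$z), ncol(x$z), x$pixel_size_nm,
              suppressWarnings(min(x$z, na.rm = TRUE)),
              suppressWarnings(max(x$z, na.rm = TRUE)), sum(is.na(x$z))))
  invisible(x)
}

# Physical pixel-centre coordinate grids (nm) for an nr x nc raster.
pixel_grid <- function(nr, nc, pixel_size_nm) {
  list(x = matrix((seq_len(nc) - 0.5) * pixel_size_nm, nr, nc, byrow = TRUE),
       y = matrix((seq_len(nr) - 0.5) * pixel_size_nm, nr, nc))
}

#' Spherical-cap calibration specimen
#'
#' A fluorescent monolayer on the convex surface of a planoconvex lens of
#' radius of curvature R, resting point-down on the mirror. The height of
#' the surface above the mirror at lateral radius r from the contact point
#' follows from the Pythagorean construction on the sphere,
#' \eqn{L(r) = R - \sqrt{R^2 - r^2}}.
#'
#' @param radius_mm Radius of curvature R of the lens (mm), > 0.
#' @param contact_center_um Contact-point position in the image plane,
#'   `c(x, y)` in micrometres.
#' @param max_field_radius_um Radius of the imaged (dye-covered) field
#'   around the contact point (um); must not exceed R.
#' @return An object of class `spherical_cap`.
#' @export
spherical_cap <- function(radius_mm, contact_center_um = c(0, 0),
                          max_field_radius_um = 1000) {
  stopifnot_scalar_num(radius_mm, "radius_mm", 0, strict_min = TRUE)
  stopifnot_scalar_num(max_field_radius_um, "max_field_radius_um", 0,
                       strict_min = TRUE)
  if (max_field_radius_um * 1e3 > radius_mm * 1e6)
    swf_config_error("max_field_radius_um must not exceed the sphere radius",
                     field = "max_field_radius_um")
  if (length(contact_center_um) != 2L || !is.numeric(contact_center_um))
    swf_config_error("contact_center_um must be c(x, y)",
                     field = "contact_center_um")
  structure(list(radius_nm = radius_mm * 1e6,
                 contact_center_nm = contact_center_um * 1e3,
                 max_field_radius_nm = max_field_radius_um * 1e3),
            class = "spherical_cap")
}

#' Height of the spherical-cap surface at a lateral radius
#'
#' @param r_nm Lateral distance(s) from the contact point (nm),
#'   0 <= r <= R.
#' @param spec A [spherical_cap()].
#' @return Height(s) above the mirror in nm: \eqn{R - \sqrt{R^2 - r^2}}.
#' @export
spherical_cap_height <- function(r_nm, spec) {
  stopifnot(inherits(spec, "spherical_cap"))
  R <- spec$radius_nm
  if (any(r_nm < 0, na.rm = TRUE))
    swf_config_error("radius must be >= 0", field = "r_nm")
  if (any(r_nm > R, na.rm = TRUE))
    swf_config_error("radius exceeds the sphere radius R", field = "r_nm")
  R - sqrt(R^2 - r_nm^2)
}

#' Height separating two fringes on a spherical cap
#'
#' The axial separation between two bright fringes of radii r1 > r2 on a
#' cap of radius R: \eqn{\sqrt{R^2-r_2^2} - \sqrt{R^2-r_1^2}}, i.e. the
#' difference of the two cap heights.
#'
#' @param r1_nm,r2_nm Fringe radii in nm with `r1_nm >= r2_nm >= 0`.
#' @param spec A [spherical_cap()].
#' @return Height separation in nm (non-negative; 0 when the radii
#'   coincide).
#' @export
fringe_height_separation <- function(r1_nm, r2_nm, spec) {
  if (any(r1_nm < r2_nm))
    swf_config_error("r1_nm must not be smaller than r2_nm", field = "r1_nm")
  spherical_cap_height(r1_nm, spec) - spherical_cap_height(r2_nm, spec)
}

#' Lateral radius at which the cap surface crosses a given height
#'
#' Inverse of [spherical_cap_height()]: \eqn{r = \sqrt{2Rz - z^2}}. Used to
#' predict fringe radii from antinode heights.
#'
#' @param z_nm Height(s) above the mirror (nm), `0 <= z <= R`.
#' @param spec A [spherical_cap()].
#' @return Radius (nm).
#' @export
spherical_cap_radius_at_height <- function(z_nm, spec) {
  stopifnot(inherits(spec, "spherical_cap"))
  R <- spec$radius_nm
  if (any(z_nm < 0 | z_nm > R, na.rm = TRUE))
    swf_config_error("height must lie in [0, R]", field = "z_nm")
  sqrt(2 * R * z_nm - z_nm^2)
}

#' Predicted antinode fringe radii on a spherical cap
#'
#' Radii at which the cap surface cuts the standing-wave antinodal planes
#' \eqn{z_k = (2k+1)\lambda/4n} within the imaged field.
#'
#' @param spec A [spherical_cap()].
#' @param cfg An [optics_config()].
#' @return Numeric vector of fringe radii (nm), innermost first.
#' @export
cap_antinode_radii <- function(spec, cfg) {
  z_max <- spherical_cap_height(spec$max_field_radius_nm, spec)
  half <- axial_fwhm(cfg)               # lambda / 4n
  k_max <- floor((z_max / half - 1) / 2)
  if (k_max < 0) return(numeric(0))
  z_k <- (2 * (0:k_max) + 1) * half
  spherical_cap_radius_at_height(z_k, spec)
}

#' Render the spherical cap as a height map
#'
#' @param spec A [spherical_cap()].
#' @param dims Raster dimensions `c(rows, cols)`.
#' @param pixel_size_nm Pixel size (nm).
#' @return A [height_map()]; pixels outside `max_field_radius` are NA.
#' @export
cap_height_map <- function(spec, dims, pixel_size_nm) {
  g <- pixel_grid(dims[1], dims[2], pixel_size_nm)
  r <- sqrt((g$x - spec$contact_center_nm[1])^2 +
            (g$y - spec$contact_center_nm[2])^2)
  r[r > spec$max_field_radius_nm] <- NA
  height_map(spherical_cap_height(r, spec), pixel_size_nm)
}

#' Discocyte (biconcave red-blood-cell) membrane specimen
#'
#' Parametric model of the normal red-cell shape: a biconcave disc about
#' 7-8 um across, about 1 um thick at the central dimple and 2.5 um at the
#' thickest ring near the rim. The thickness profile is a quartic-in-rho^2
#' family \eqn{T(\rho) = \sqrt{1-\rho^2}(C_0 + C_2\rho^2 + C_4\rho^4)}
#' (Evans-Fung style), with \eqn{\rho = 2r/\textrm{diameter}} and the
#' coefficients solved so that T(0) equals the centre thickness and the
#' maximum of T equals the rim thickness (attained at `rho_rim`).
#'
#' @param diameter_um Cell diameter (um); physiological range roughly 6-9.
#' @param center_thickness_um Thickness at the dimple centre (um).
#' @param rim_thickness_um Maximum thickness at the peripheral ring (um);
#'   must exceed the centre thickness.
#' @param standoff_um Gap between the mirror and the lowest membrane point
#'   (um), >= 0 (cells settled on poly-L-lysine: 0).
#' @param center_um Cell centre `c(x, y)` in the image plane (um).
#' @param tilt Small-angle tilt `c(about x, about y)` in radians.
#' @param rho_rim Normalised radius of the thickest ring (default 0.85).
#' @return An object of class `discocyte` with solved thickness
#'   coefficients `coef = c(C0, C2, C4)` in nm.
#' @export
discocyte <- function(diameter_um = 7.8, center_thickness_um = 1.0,
                      rim_thickness_um = 2.5, standoff_um = 0,
                      center_um = c(0, 0), tilt = c(0, 0), rho_rim = 0.85) {
  stopifnot_scalar_num(diameter_um, "diameter_um", 0, strict_min = TRUE)
  stopifnot_scalar_num(center_thickness_um, "center_thickness_um", 0,
                       strict_min = TRUE)
  stopifnot_scalar_num(rim_thickness_um, "rim_thickness_um", 0,
                       strict_min = TRUE)
  stopifnot_scalar_num(standoff_um, "standoff_um", 0)
  if (rim_thickness_um <= center_thickness_um)
    swf_config_error("rim_thickness_um must exceed center_thickness_um",
                     field = "rim_thickness_um")
  # Solve C2, C4 (linear): T(rho_rim) = rim, T'(rho_rim) = 0, C0 = centre.
  C0 <- center_thickness_um * 1e3
  rim <- rim_thickness_um * 1e3
  p <- rho_rim; s <- sqrt(1 - p^2)
  A <- rbind(c(s * p^2, s * p^4),
             c(-p / s * p^2 + 2 * s * p, -p / s * p^4 + 4 * s * p^3))
  b <- c(rim - s * C0, p / s * C0)
  co <- tryCatch(solve(A, b), error = function(e)
    swf_config_error("thickness coefficient solve failed", field = "rho_rim"))
  cf <- c(C0, co)
  # Validate: positive thickness inside, global max at rho_rim, centre is
  # the interior minimum.
  rho <- seq(0, 1, length.out = 2001)
  Tv <- sqrt(1 - rho^2) * (cf[1] + cf[2] * rho^2 + cf[3] * rho^4)
  if (any(Tv < 0) || abs(max(Tv) - rim) > 1e-6 * rim ||
      min(Tv[rho < rho_rim]) < C0 - 1e-6 * C0)
    swf_config_error("incompatible thickness constraints (no valid biconcave profile)",
                     field = "rim_thickness_um")
  structure(list(diameter_nm = diameter_um * 1e3,
                 center_thickness_nm = C0,
                 rim_thickness_nm = rim,
                 standoff_nm = standoff_um * 1e3,
                 center_nm = center_um * 1e3,
                 tilt = tilt, rho_rim = rho_rim, coef = cf),
            class = "discocyte")
}

#' Discocyte membrane thickness at a normalised radius
#'
#' @param rho Normalised radius `2 r / diameter` in [0, 1].
#' @param spec A [discocyte()].
#' @return Thickness in nm (0 outside the footprint).
#' @export
discocyte_thickness <- function(rho, spec) {
  stopifnot(inherits(spec, "discocyte"))
  cf <- spec$coef
  out <- ifelse(rho <= 1,
                sqrt(pmax(1 - rho^2, 0)) * (cf[1] + cf[2] * rho^2 + cf[3] * rho^4),
                0)
  pmax(out, 0)
}

#' Upper and lower membrane height maps of a discocyte above the mirror
#'
#' The shell mid-plane sits at `standoff + rim_thickness/2`, so the lowest
#' point of the lower membrane (the rim ring) rests at the standoff height;
#' upper and lower sheets are mid-plane +/- T/2, then tilted about the cell
#' centre. A tilt is compensated with a vertical offset so the lowest
#' membrane point stays at the standoff height (the cell rests on the
#' substrate). Outside the footprint both sheets are NA.
#'
#' @param spec A [discocyte()].
#' @param dims Raster dimensions `c(rows, cols)`.
#' @param pixel_size_nm Pixel size (nm).
#' @return `list(upper =, lower =)` of [height_map()]s.
#' @export
discocyte_surfaces <- function(spec, dims, pixel_size_nm) {
  stopifnot(inherits(spec, "discocyte"))
  g <- pixel_grid(dims[1], dims[2], pixel_size_nm)
  dx <- g$x - spec$center_nm[1]
  dy <- g$y - spec$center_nm[2]
  rho <- 2 * sqrt(dx^2 + dy^2) / spec$diameter_nm
  inside <- rho <= 1
  Tm <- matrix(NA_real_, dims[1], dims[2])
  Tm[inside] <- discocyte_thickness(rho[inside], spec)
  mid <- spec$rim_thickness_nm / 2
  tiltz <- spec$tilt[2] * dx + spec$tilt[1] * dy
  upper <- mid + Tm / 2 + tiltz
  lower <- mid - Tm / 2 + tiltz
  # rest the cell: lowest membrane point at the standoff height
  lift <- spec$standoff_nm - min(lower, na.rm = TRUE)
  upper <- upper + lift; lower <- lower + lift
  list(upper = height_map(upper, pixel_size_nm),
       lower = height_map(lower, pixel_size_nm))
}
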