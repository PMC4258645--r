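# Disk formats: grayscale TIFF rasters with JSON sidecars carrying scale,
# provenance and seed. Intensities are stored as 16-bit integers with a
# linear counts-per-level scale; height maps as 32-bit float TIFF with the
# z range normalised to [0, 1] (offset/scale in the sidecar) plus a second
# float channel holding the validity mask.

sidecar_path <- function(path) paste0(path, ".json")

write_sidecar <- function(path, x) {
  jsonlite::write_json(x, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
}

read_sidecar <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc)) return(NULL)
  jsonlite::read_json(sc, simplifyVector = TRUE)
}

#' Write a fringe image as 16-bit TIFF plus JSON sidecar
#'
#' @param img A [fringe_image()].
#' @param path Output TIFF path; the sidecar is written to
#'   `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_fringe_image <- function(img, path) {
  stopifnot(inherits(img, "fringe_image"))
  top <- max(img$data, 1e-12)
  ok <- try(tiff::writeTIFF(img$data / top, path, bits.per.sample = 16L),
            silent = TRUE)
  if (inherits(ok, "try-error"))
    swf_io_error(sprintf("cannot write TIFF '%s'", path))
  write_sidecar(path, list(type = "fringe_image",
                           pixel_size_nm = img$pixel_size_nm,
                           counts_per_level = top / 65535,
                           metadata = img$metadata))
  invisible(path)
}

#' Read a fringe image written by [write_fringe_image()]
#'
#' Plain grayscale TIFFs without a sidecar are accepted; their pixel size
#' must then be supplied.
#'
#' @param path TIFF path.
#' @param pixel_size_nm Pixel size override (nm), required when no sidecar
#'   is present.
#' @return A [fringe_image()].
#' @export
read_fringe_image <- function(path, pixel_size_nm = NULL) {
  if (!file.exists(path)) swf_io_error(sprintf("no such file '%s'", path))
  raw <- try(tiff::readTIFF(path), silent = TRUE)
  if (inherits(raw, "try-error"))
    swf_io_error(sprintf("cannot read TIFF '%s'", path))
  if (length(dim(raw)) == 3) raw <- raw[, , 1]
  sc <- read_sidecar(path)
  if (is.null(pixel_size_nm))
    pixel_size_nm <- sc$pixel_size_nm
  if (is.null(pixel_size_nm))
    swf_config_error("pixel size unknown: no sidecar and no override",
                     field = "pixel_size_nm")
  scale <- if (!is.null(sc$counts_per_level)) sc$counts_per_level * 65535 else 1
  fringe_image(raw * scale, pixel_size_nm,
               if (!is.null(sc$metadata)) sc$metadata else list())
}

#' Write a height map as 32-bit float TIFF plus JSON sidecar
#'
#' Channel 1 holds the height normalised to `[0, 1]` by the offset/scale
#' recorded in the sidecar (`z = offset_nm + value * scale_nm`); channel 2
#' is the validity mask (1 = defined).
#'
#' @param hm A [height_map()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_height_map <- function(hm, path) {
  stopifnot(inherits(hm, "height_map"))
  rng <- range(hm$z, na.rm = TRUE)
  scale <- max(rng[2] - rng[1], 1e-12)
  norm <- (hm$z - rng[1]) / scale
  mask <- !is.na(hm$z)
  norm[!mask] <- 0
  arr <- array(c(norm, mask * 1), dim = c(dim(hm$z), 2))
  ok <- try(tiff::writeTIFF(arr, path, bits.per.sample = 32L), silent = TRUE)
  if (inherits(ok, "try-error"))
    swf_io_error(sprintf("cannot write TIFF '%s'", path))
  write_sidecar(path, list(type = "height_map",
                           pixel_size_nm = hm$pixel_size_nm,
                           offset_nm = rng[1], scale_nm = scale))
  invisible(path)
}

#' Read a height map written by [write_height_map()]
#'
#' @param path TIFF path (sidecar required).
#' @return A [height_map()].
#' @export
read_height_map <- function(path) {
  if (!file.exists(path)) swf_io_error(sprintf("no such file '%s'", path))
  sc <- read_sidecar(path)
  if (is.null(sc) || is.null(sc$offset_nm))
    swf_io_error(sprintf("missing or invalid sidecar for '%s'", path))
  raw <- try(suppressWarnings(tiff::readTIFF(path)), silent = TRUE)
  if (inherits(raw, "try-error"))
    swf_io_error(sprintf("cannot read TIFF '%s'", path))
  z <- sc$offset_nm + raw[, , 1] * sc$scale_nm
  z[raw[, , 2] < 0.5] <- NA
  height_map(z, sc$pixel_size_nm)
}

#' Write fringe contours as GeoJSON-style JSON
#'
#' Each contour becomes a feature with a LineString of `[x, y]` positions
#' in nm and properties `strength`, `antinode_index`, `z_nm`.
#'
#' @param contours A `contour_set`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_contours_json <- function(contours, path) {
  stopifnot(inherits(contours, "contour_set"))
  feats <- lapply(unclass(contours), function(cc) {
    list(type = "Feature",
         geometry = list(type = "LineString",
                         coordinates = unname(split(cc$xy, row(cc$xy)))),
         properties = list(strength = cc$strength,
                           antinode_index = cc$antinode_index,
                           z_nm = cc$z_nm))
  })
  jsonlite::write_json(
    list(type = "FeatureCollection",
         properties = list(units = "nm",
                           pixel_size_nm = attr(contours, "pixel_size_nm"),
                           base_index_assumed =
                             attr(contours, "base_index_assumed")),
         features = feats),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Export a radial profile or peak set as CSV
#'
#' @param x A `radial_profile` or `fringe_peaks` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_analysis_csv <- function(x, path) {
  df <- if (inherits(x, "radial_profile"))
    data.frame(radius_nm = x$radius_nm, intensity = x$intensity)
  else if (inherits(x, "fringe_peaks")) as.data.frame(x)
  else swf_config_error("x must be a radial_profile or fringe_peaks",
                        field = "x")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a run configuration from YAML or JSON
#'
#' @param path Configuration file; `.json` is parsed with jsonlite,
#'   anything else with yaml.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) swf_io_error(sprintf("no such file '%s'", path))
  out <- try(if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
             else yaml::read_yaml(path), silent = TRUE)
  if (inherits(out, "try-error") || !is.list(out))
    swf_config_error(sprintf("cannot parse config '%s'", path))
  out
}
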