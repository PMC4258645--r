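# Contour-based 3D mapping: fringe ridges -> antinode heights -> surface.

# Bilinear sample of matrix S at fractional (row, col) positions.
bilinear_sample <- function(S, rq, cq) {
  nr <- nrow(S); nc <- ncol(S)
  out_dim <- dim(rq)
  rq <- pmin(pmax(as.vector(rq), 1), nr)
  cq <- pmin(pmax(as.vector(cq), 1), nc)
  r0 <- pmin(floor(rq), nr - 1); c0 <- pmin(floor(cq), nc - 1)
  fr <- rq - r0; fc <- cq - c0
  v <- S[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    S[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    S[cbind(r0, c0 + 1)] * (1 - fr) * fc +
    S[cbind(r0 + 1, c0 + 1)] * fr * fc
  if (!is.null(out_dim)) dim(v) <- out_dim
  v
}

#' Extract fringe ridge contours from an image
#'
#' Detects the bright fringe ridges of a (smoothed) image as local maxima
#' transverse to the ridge direction: at each pixel the Hessian's most
#' negative principal curvature direction is computed and the pixel is kept
#' if its intensity exceeds both bilinearly interpolated neighbours one
#' pixel away along that direction (non-maximum suppression), exceeds
#' `ridge_threshold * max(image)`, and has negative transverse curvature.
#' Surviving pixels are grouped into connected chains, fragments shorter
#' than 10 pixels are dropped, and each chain is ordered into a polyline by
#' angle about its centroid (fringe contours of the specimens modelled here
#' are closed, near-circular curves).
#'
#' @param img A [fringe_image()].
#' @param smoothing_sigma_nm Gaussian smoothing sigma before ridge
#'   detection (nm; default one pixel).
#' @param ridge_threshold Intensity floor as a fraction of the smoothed
#'   image maximum.
#' @return An object of class `contour_set`: a list of contours, each with
#'   `xy` (n x 2 matrix of positions in nm), `strength` (mean ridge
#'   intensity relative to the image maximum), `antinode_index` (NA until
#'   assigned) and `z_nm` (NA until assigned). May be empty.
#' @export
extract_fringe_contours <- function(img, smoothing_sigma_nm = NULL,
                                    ridge_threshold = 0.1) {
  stopifnot(inherits(img, "fringe_image"))
  ps <- img$pixel_size_nm
  if (is.null(smoothing_sigma_nm)) smoothing_sigma_nm <- ps
  S <- as.matrix(EBImage::gblur(img$data, sigma = smoothing_sigma_nm / ps))
  nr <- nrow(S); nc <- ncol(S)
  empty <- structure(list(), class = "contour_set", pixel_size_nm = ps,
                     dims = c(nr, nc))
  if (max(S) <= min(S)) return(empty)
  # Hessian by central differences (interior pixels only).
  Sxx <- Syy <- Sxy <- matrix(0, nr, nc)
  Sxx[, 2:(nc - 1)] <- S[, 3:nc] - 2 * S[, 2:(nc - 1)] + S[, 1:(nc - 2)]
  Syy[2:(nr - 1), ] <- S[3:nr, ] - 2 * S[2:(nr - 1), ] + S[1:(nr - 2), ]
  Sxy[2:(nr - 1), 2:(nc - 1)] <-
    (S[3:nr, 3:nc] - S[3:nr, 1:(nc - 2)] -
       S[1:(nr - 2), 3:nc] + S[1:(nr - 2), 1:(nc - 2)]) / 4
  disc <- sqrt((Sxx - Syy)^2 + 4 * Sxy^2)
  l2 <- (Sxx + Syy - disc) / 2              # most negative curvature
  l1 <- (Sxx + Syy + disc) / 2
  # Eigenvector (vx, vy) of l2: direction of steepest transverse descent.
  vx <- l2 - Syy; vy <- Sxy
  swap <- abs(Sxy) < 1e-12 & Sxx <= Syy
  vx[swap] <- 1; vy[swap] <- 0
  swap2 <- abs(Sxy) < 1e-12 & Sxx > Syy
  vx[swap2] <- 0; vy[swap2] <- 1
  nv <- sqrt(vx^2 + vy^2); nv[nv == 0] <- 1
  vx <- vx / nv; vy <- vy / nv
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  up <- bilinear_sample(S, rows + vy, cols + vx)
  dn <- bilinear_sample(S, rows - vy, cols - vx)
  # Keep crest pixels only: transverse curvature must be negative,
  # dominate the along-ridge curvature, and the local gradient must be
  # small compared with the curvature (a true crest pixel lies within
  # half a pixel of the stationary line, so |grad S| <~ 0.5 |l2| in pixel
  # units, while flank pixels carry the full fringe slope). Together these
  # reject the gentle tangential-curvature shoulders flanking each ring.
  gx <- gy <- matrix(0, nr, nc)
  gx[, 2:(nc - 1)] <- (S[, 3:nc] - S[, 1:(nc - 2)]) / 2
  gy[2:(nr - 1), ] <- (S[3:nr, ] - S[1:(nr - 2), ]) / 2
  ridge <- S >= up & S >= dn & l2 < 0 & abs(l2) > abs(l1) &
    sqrt(gx^2 + gy^2) < 0.75 * abs(l2) &
    S >= ridge_threshold * max(S)
  ridge[c(1, nr), ] <- FALSE; ridge[, c(1, nc)] <- FALSE
  if (!any(ridge)) return(empty)
  # Label 8-connected chains: dilate to bridge diagonals, then label.
  dil <- EBImage::dilate(ridge * 1, EBImage::makeBrush(3, "box"))
  lab <- EBImage::imageData(EBImage::bwlabel(dil))
  ids <- lab[ridge]
  pix <- which(ridge, arr.ind = TRUE)
  contours <- list()
  for (id in sort(unique(ids))) {
    pts <- pix[ids == id, , drop = FALSE]
    if (nrow(pts) < 10) next
    x <- (pts[, 2] - 0.5) * ps; y <- (pts[, 1] - 0.5) * ps
    ord <- order(atan2(y - mean(y), x - mean(x)))
    contours[[length(contours) + 1]] <-
      list(xy = cbind(x = x[ord], y = y[ord]),
           strength = mean(S[pts]) / max(S),
           antinode_index = NA_integer_, z_nm = NA_real_)
  }
  structure(contours, class = "contour_set", pixel_size_nm = ps,
            dims = c(nr, nc))
}

#' @export
print.contour_set <- function(x, ...) {
  cat(sprintf("<contour_set> %d contour(s)", length(x)))
  if (length(x) && !is.na(x[[1]]$antinode_index))
    cat(", indices assigned")
  cat("\n")
  invisible(x)
}

# Ray-casting point-in-polygon; poly is an n x 2 matrix, point (px, py).
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  j <- c(n, seq_len(n - 1))
  xi <- poly[, 1]; yi <- poly[, 2]
  xj <- poly[j, 1]; yj <- poly[j, 2]
  cross <- (yi > py) != (yj > py)
  if (!any(cross)) return(FALSE)
  xint <- xj[cross] + (py - yj[cross]) / (yi[cross] - yj[cross]) *
    (xi[cross] - xj[cross])
  sum(xint > px) %% 2 == 1
}

# Fraction of (subsampled) vertices of contour a inside contour b.
containment_fraction <- function(a, b, n_sample = 24) {
  idx <- unique(round(seq(1, nrow(a$xy), length.out = n_sample)))
  mean(vapply(idx, function(i)
    point_in_polygon(a$xy[i, 1], a$xy[i, 2], b$xy), logical(1)))
}

#' Assign antinode indices and heights to nested fringe contours
#'
#' Verifies that the contours form a single nested family (every pair is
#' either fully contained or fully disjoint; anything in between raises an
#' `swf_ambiguous_topology` error), orders them by containment depth, and
#' assigns consecutive antinode indices starting at `base_index`:
#' `nested_inward` counts up from the outermost contour inwards,
#' `nested_outward` from the innermost outwards (the physical ordering for
#' a surface rising away from a central contact point). Each contour then
#' receives the height of its antinodal plane,
#' \eqn{z = (2\,\textrm{index}+1)\lambda/4n}.
#'
#' The absolute index is unidentifiable from a single broadband image;
#' `base_index` defaults to 0 (surface touching the mirror) and the
#' assumption is recorded on the returned object. See [rank_base_index()]
#' for the moire-amplitude disambiguation hint.
#'
#' @param contours A `contour_set` from [extract_fringe_contours()].
#' @param cfg An [optics_config()].
#' @param mode `"nested_outward"` or `"nested_inward"`.
#' @param base_index Antinode index of the first contour in the chosen
#'   order, >= 0.
#' @return The `contour_set` with `antinode_index` and `z_nm` set, ordered
#'   by increasing index; attribute `base_index_assumed` records the
#'   ambiguity.
#' @export
assign_antinode_indices <- function(contours, cfg,
                                    mode = c("nested_outward",
                                             "nested_inward"),
                                    base_index = 0L) {
  mode <- match.arg(mode)
  stopifnot(inherits(contours, "contour_set"), inherits(cfg, "optics_config"))
  k <- length(contours)
  if (k == 0) return(contours)
  inside <- matrix(FALSE, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    f <- containment_fraction(contours[[i]], contours[[j]])
    if (f > 0.05 && f < 0.95)
      swf_analysis_error(
        sprintf("contours %d and %d cross: nesting is ambiguous", i, j),
        "swf_ambiguous_topology")
    inside[i, j] <- f >= 0.95
  }
  depth <- rowSums(inside)
  if (anyDuplicated(depth))
    swf_analysis_error(
      "contours do not form a single nested chain: nesting is ambiguous",
      "swf_ambiguous_topology")
  ord <- if (mode == "nested_inward") order(depth) else order(-depth)
  out <- contours[ord]
  half <- axial_fwhm(cfg)                   # lambda / 4n
  for (i in seq_along(out)) {
    idx <- base_index + i - 1L
    out[[i]]$antinode_index <- idx
    out[[i]]$z_nm <- (2 * idx + 1) * half
  }
  structure(out, class = "contour_set",
            pixel_size_nm = attr(contours, "pixel_size_nm"),
            dims = attr(contours, "dims"),
            base_index_assumed = base_index, mode = mode)
}

#' Interpolate a surface from height-assigned contours
#'
#' Linear interpolation between contour lines: every grid point takes the
#' distance-weighted mean of the heights of its two nearest contours,
#' `z = (d2 z1 + d1 z2) / (d1 + d2)` — on a contour the contour's own
#' height, midway between two contours their mean. Distances are computed
#' with Euclidean distance maps of the rasterised contours. Grid points
#' outside the convex hull of all contour points are masked (NA). The
#' result is bounded by the assigned heights.
#'
#' @param contours A `contour_set` with `z_nm` assigned for >= 2 contours.
#' @param grid_pixel_size_nm Output grid pitch (nm; default the source
#'   image pixel size).
#' @param dims Output raster dimensions (default the source image dims).
#' @return A [height_map()].
#' @export
interpolate_surface <- function(contours, grid_pixel_size_nm = NULL,
                                dims = NULL) {
  stopifnot(inherits(contours, "contour_set"))
  zs <- vapply(contours, function(cc) cc$z_nm, numeric(1))
  if (sum(!is.na(zs)) < 2)
    swf_analysis_error("need >= 2 contours with assigned heights")
  src_ps <- attr(contours, "pixel_size_nm")
  src_dims <- attr(contours, "dims")
  contours <- unclass(contours)[!is.na(zs)]; zs <- zs[!is.na(zs)]
  if (is.null(grid_pixel_size_nm)) grid_pixel_size_nm <- src_ps
  ps <- grid_pixel_size_nm
  if (is.null(dims)) {
    dims <- src_dims
    if (!is.null(dims) && !is.null(src_ps))
      dims <- pmax(ceiling(dims * src_ps / ps), 2)
  }
  if (is.null(dims)) {
    all_xy <- do.call(rbind, lapply(contours, `[[`, "xy"))
    dims <- c(ceiling(max(all_xy[, 2]) / ps) + 1,
              ceiling(max(all_xy[, 1]) / ps) + 1)
  }
  nr <- dims[1]; nc <- dims[2]
  d1 <- matrix(Inf, nr, nc); d2 <- matrix(Inf, nr, nc)
  z1 <- matrix(NA_real_, nr, nc); z2 <- matrix(NA_real_, nr, nc)
  for (i in seq_along(contours)) {
    xy <- contours[[i]]$xy
    rr <- pmin(pmax(ceiling(xy[, 2] / ps), 1), nr)
    cc_ <- pmin(pmax(ceiling(xy[, 1] / ps), 1), nc)
    mask <- matrix(1, nr, nc)
    mask[cbind(rr, cc_)] <- 0
    d <- as.matrix(EBImage::distmap(mask)) * ps
    better1 <- d < d1
    d2[better1] <- d1[better1]; z2[better1] <- z1[better1]
    d1[better1] <- d[better1]; z1[better1] <- zs[i]
    better2 <- !better1 & d < d2
    d2[better2] <- d[better2]; z2[better2] <- zs[i]
  }
  z <- (z1 * d2 + z2 * d1) / (d1 + d2)
  on_contour <- d1 == 0
  z[on_contour] <- z1[on_contour]
  # mask outside the convex hull of all contour points
  all_xy <- do.call(rbind, lapply(contours, `[[`, "xy"))
  hull <- all_xy[grDevices::chull(all_xy), , drop = FALSE]
  g <- pixel_grid(nr, nc, ps)
  inside <- rep(TRUE, nr * nc)
  nh <- nrow(hull)
  # hull from chull is clockwise in standard orientation; test via
  # consistent half-plane signs
  sgn <- 0
  for (i in seq_len(nh)) {
    j <- if (i == nh) 1 else i + 1
    ex <- hull[j, 1] - hull[i, 1]; ey <- hull[j, 2] - hull[i, 2]
    s <- ex * (as.vector(g$y) - hull[i, 2]) -
      ey * (as.vector(g$x) - hull[i, 1])
    if (sgn == 0) sgn <- sign(s[which.max(abs(s))])
    inside <- inside & (sgn * s >= -1e-9)
  }
  z[!matrix(inside, nr, nc)] <- NA
  height_map(pmax(z, 0), ps)
}

#' Root-mean-square height error between two maps
#'
#' @param recon,truth [height_map()]s on the same grid (equal dimensions
#'   and pixel size); the RMSE is taken over the pixels where both are
#'   defined.
#' @return RMSE in nm.
#' @export
reconstruction_rmse <- function(recon, truth) {
  stopifnot(inherits(recon, "height_map"), inherits(truth, "height_map"))
  if (!all(dim(recon$z) == dim(truth$z)))
    swf_config_error("height maps must share a grid", field = "truth")
  d <- recon$z - truth$z
  if (all(is.na(d)))
    swf_analysis_error("no overlap between reconstruction and truth masks")
  sqrt(mean(d^2, na.rm = TRUE))
}

#' Reconstruct a surface from a fringe image end to end
#'
#' Convenience wrapper: ridge-contour extraction, nested index assignment
#' and contour interpolation.
#'
#' @param img A [fringe_image()].
#' @param cfg An [optics_config()].
#' @param mode Nesting direction (see [assign_antinode_indices()]).
#' @param base_index Base antinode index.
#' @param smoothing_sigma_nm,ridge_threshold Passed to
#'   [extract_fringe_contours()].
#' @return `list(surface = height_map, contours = contour_set)`.
#' @export
reconstruct_surface <- function(img, cfg, mode = "nested_outward",
                                base_index = 0L, smoothing_sigma_nm = NULL,
                                ridge_threshold = 0.1) {
  contours <- extract_fringe_contours(img, smoothing_sigma_nm,
                                      ridge_threshold)
  if (length(contours) < 2)
    swf_analysis_error("fewer than 2 fringe contours found")
  contours <- assign_antinode_indices(contours, cfg, mode, base_index)
  list(surface = interpolate_surface(contours), contours = contours)
}
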