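# Measurement chain: centre finding -> radial profile -> peak detection
# with subpixel refinement -> radius-to-height mapping -> spacing and
# moire-envelope estimation.

# Azimuthal-symmetry score of a candidate centre: the variance of the
# azimuthal bin means (weighted by bin occupancy), normalised by the total
# pixel variance. Sharp concentric structure about the true centre keeps
# the fringe contrast in the bin means; a wrong centre averages it away.
center_score <- function(v, xg, yg, cx, cy, bw) {
  r <- sqrt((xg - cx)^2 + (yg - cy)^2)
  idx <- floor(r / bw) + 1
  sums <- rowsum(v, idx)
  cnts <- rowsum(rep(1, length(v)), idx)
  m <- sums / cnts
  grand <- sum(sums) / sum(cnts)
  sum(cnts * (m - grand)^2) / sum(cnts) / stats::var(v)
}

#' Locate the centre of a concentric fringe pattern
#'
#' Finds the centre of radial symmetry — physically, the specimen-mirror
#' contact point, which is dark because the mirror is the first node — by
#' maximising an azimuthal-symmetry score (normalised variance of azimuthal
#' means across radial bins) over candidate centres, with Nelder-Mead
#' subpixel refinement started at the intensity centroid.
#'
#' @param img A [fringe_image()].
#' @param bin_width_nm Radial bin width for the score (default: one pixel).
#' @param min_score Score threshold below which the image is declared to
#'   contain no symmetric structure (error class `swf_centre_not_found`).
#' @return Numeric `c(x, y)` centre in continuous pixel units (pixel i's
#'   centre is at i - 0.5).
#' @export
find_fringe_center <- function(img, bin_width_nm = NULL, min_score = 0.05) {
  stopifnot(inherits(img, "fringe_image"))
  v <- as.vector(img$data)
  if (stats::var(v) == 0)
    swf_analysis_error("no symmetric structure: image is uniform",
                       "swf_centre_not_found")
  nr <- nrow(img$data); nc <- ncol(img$data)
  if (is.null(bin_width_nm)) bin_width_nm <- img$pixel_size_nm
  g <- pixel_grid(nr, nc, 1)            # work in pixel units
  xg <- as.vector(g$x); yg <- as.vector(g$y)
  bw <- bin_width_nm / img$pixel_size_nm
  w <- v - min(v)
  start <- c(sum(xg * w) / sum(w), sum(yg * w) / sum(w))
  fit <- stats::optim(start, function(p) {
    if (p[1] < 0 || p[1] > nc || p[2] < 0 || p[2] > nr) return(0)
    -center_score(v, xg, yg, p[1], p[2], bw)
  }, method = "Nelder-Mead",
  control = list(reltol = 1e-7, maxit = 300))
  if (-fit$value < min_score)
    swf_analysis_error(
      sprintf("no symmetric structure: symmetry score %.3g < %.3g",
              -fit$value, min_score), "swf_centre_not_found")
  c(x = fit$par[1], y = fit$par[2])
}

#' Radial intensity profile about a centre
#'
#' Azimuthal mean of pixel intensities in annular bins (the default), or a
#' single-ray profile along one radial direction for strict fidelity to a
#' line-profile measurement.
#'
#' @param img A [fringe_image()].
#' @param center_px Centre `c(x, y)` in pixel units; found with
#'   [find_fringe_center()] when NULL.
#' @param bin_width_nm Annulus width (nm), >= one pixel.
#' @param method `"azimuthal"` (mean over each annulus) or `"ray"`.
#' @param ray_angle Direction (radians) for `method = "ray"`; pixels within
#'   half a bin of the ray are used.
#' @return An object of class `radial_profile`: list with `radius_nm` (bin
#'   centres, strictly increasing, empty bins dropped), `intensity`,
#'   `bin_width_nm`, `center_px`.
#' @export
radial_profile <- function(img, center_px = NULL, bin_width_nm = NULL,
                           method = c("azimuthal", "ray"), ray_angle = 0) {
  stopifnot(inherits(img, "fringe_image"))
  method <- match.arg(method)
  if (is.null(center_px)) center_px <- find_fringe_center(img)
  if (is.null(bin_width_nm)) bin_width_nm <- img$pixel_size_nm
  if (bin_width_nm < img$pixel_size_nm)
    swf_config_error("bin_width_nm must be >= the pixel size",
                     field = "bin_width_nm")
  nr <- nrow(img$data); nc <- ncol(img$data)
  if (center_px[1] < 0 || center_px[1] > nc ||
      center_px[2] < 0 || center_px[2] > nr)
    swf_config_error("center_px lies outside the image", field = "center_px")
  g <- pixel_grid(nr, nc, img$pixel_size_nm)
  dx <- g$x - center_px[1] * img$pixel_size_nm
  dy <- g$y - center_px[2] * img$pixel_size_nm
  r <- sqrt(dx^2 + dy^2)
  v <- img$data
  if (method == "ray") {
    ang <- atan2(dy, dx)
    d <- abs(r * sin(ang - ray_angle))       # perpendicular distance to ray
    keep <- d <= bin_width_nm / 2 & cos(ang - ray_angle) >= 0
    r <- r[keep]; v <- v[keep]
  }
  idx <- floor(as.vector(r) / bin_width_nm) + 1
  sums <- rowsum(as.vector(v), idx)
  cnts <- rowsum(rep(1, length(idx)), idx)
  bins <- as.integer(rownames(sums))
  structure(list(radius_nm = (bins - 0.5) * bin_width_nm,
                 intensity = as.vector(sums / cnts),
                 bin_width_nm = bin_width_nm, center_px = center_px),
            class = "radial_profile")
}

# Topographic prominence of the local maxima of y.
local_maxima_prominence <- function(y) {
  n <- length(y)
  if (n < 3) return(list(i = integer(0), prom = numeric(0)))
  i <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1
  prom <- vapply(i, function(k) {
    h <- y[k]
    left <- y[seq_len(k - 1)]
    hl <- which(left > h)
    ml <- if (length(hl)) min(left[(max(hl) + 1):(k - 1)]) else min(left)
    right <- y[(k + 1):n]
    hr <- which(right > h)
    mr <- if (length(hr)) min(right[seq_len(min(hr) - 1)]) else min(right)
    h - max(ml, mr)
  }, numeric(1))
  list(i = i, prom = prom)
}

# Subpixel refinement: bounded minimisation of the negated cubic
# interpolant of the profile within one sample either side of each
# detected maximum (the flipped-function-and-fminbnd procedure).
refine_maxima <- function(x, y, idx) {
  spl <- stats::splinefun(x, y, method = "fmm")
  t(vapply(idx, function(k) {
    lo <- x[max(k - 1, 1)]; hi <- x[min(k + 1, length(x))]
    opt <- stats::optimize(function(r) -spl(r), interval = c(lo, hi))
    c(opt$minimum, -opt$objective)
  }, numeric(2)))
}

#' Detect and refine fringe peaks in a radial profile
#'
#' Local maxima whose topographic prominence exceeds
#' `min_prominence * (max - min)` of the profile, separated by at least
#' `min_separation_nm` (enforced greedily, keeping the larger peak). Each
#' retained maximum is refined to subpixel radius by bounded scalar
#' minimisation of the negated cubic-interpolated profile within one bin
#' either side.
#'
#' @param profile A [radial_profile()].
#' @param min_prominence Prominence threshold as a fraction of the profile
#'   range.
#' @param min_separation_nm Minimum radial separation between peaks (nm).
#' @return An object of class `fringe_peaks`: data frame with
#'   `radius_nm` (strictly increasing) and `amplitude`; height columns
#'   (`z_nm`, `antinode_index`) are filled by [radii_to_heights()].
#' @export
detect_peaks <- function(profile, min_prominence = 0.1,
                         min_separation_nm = 0) {
  stopifnot(inherits(profile, "radial_profile"))
  x <- profile$radius_nm; y <- profile$intensity
  if (length(y) < 3)
    swf_analysis_error("profile has fewer than 3 samples", "swf_no_peaks")
  lm <- local_maxima_prominence(y)
  keep <- lm$prom >= min_prominence * (max(y) - min(y))
  idx <- lm$i[keep]; prom <- lm$prom[keep]
  if (!length(idx))
    swf_analysis_error("no peaks found in radial profile", "swf_no_peaks")
  if (min_separation_nm > 0) {
    ord <- order(prom, decreasing = TRUE)
    chosen <- integer(0)
    for (k in idx[ord])
      if (!length(chosen) ||
          all(abs(x[k] - x[chosen]) >= min_separation_nm))
        chosen <- c(chosen, k)
    idx <- sort(chosen)
  }
  ref <- refine_maxima(x, y, idx)
  out <- data.frame(radius_nm = ref[, 1], amplitude = ref[, 2])
  out <- out[order(out$radius_nm), ]
  rownames(out) <- NULL
  structure(out, class = c("fringe_peaks", "data.frame"),
            bin_width_nm = profile$bin_width_nm)
}

#' Convert fringe radii to heights above the mirror
#'
#' Maps each peak radius through the spherical-cap geometry,
#' `z = R - sqrt(R^2 - r^2)`, and assigns antinode indices 0, 1, 2, ... in
#' order of increasing height. When `cfg` is supplied, peaks closer in
#' height than `lambda/8n` are merged (the larger amplitude wins) to guard
#' against double detections where fringes crowd at the field edge.
#'
#' @param peaks A `fringe_peaks` object from [detect_peaks()].
#' @param spec A [spherical_cap()].
#' @param cfg Optional [optics_config()] enabling the close-peak merge.
#' @return The `fringe_peaks` object with `z_nm` and `antinode_index`
#'   columns filled.
#' @export
radii_to_heights <- function(peaks, spec, cfg = NULL) {
  stopifnot(inherits(peaks, "fringe_peaks"), inherits(spec, "spherical_cap"))
  if (any(peaks$radius_nm > spec$radius_nm))
    swf_analysis_error("peak radius exceeds the cap radius R")
  z <- spherical_cap_height(peaks$radius_nm, spec)
  out <- as.data.frame(peaks)
  out$z_nm <- z
  out <- out[order(out$z_nm), ]
  if (!is.null(cfg)) {
    min_dz <- antinode_spacing(cfg) / 4       # lambda / 8n
    keep <- rep(TRUE, nrow(out))
    last <- 1
    for (j in seq_len(nrow(out))[-1]) {
      if (out$z_nm[j] - out$z_nm[last] < min_dz) {
        if (out$amplitude[j] > out$amplitude[last]) {
          keep[last] <- FALSE; last <- j
        } else keep[j] <- FALSE
      } else last <- j
    }
    out <- out[keep, ]
  }
  out$antinode_index <- seq_len(nrow(out)) - 1L
  rownames(out) <- NULL
  structure(out, class = c("fringe_peaks", "data.frame"),
            bin_width_nm = attr(peaks, "bin_width_nm"))
}

#' Estimate the antinodal spacing from a height-mapped peak set
#'
#' Default estimator is the least-squares slope of height against antinode
#' index (less noise-sensitive than successive differences, which are also
#' available via `method = "diff"`).
#'
#' @param peaks A `fringe_peaks` object with `z_nm` and `antinode_index`
#'   filled ([radii_to_heights()]).
#' @param method `"regression"` (slope of z ~ index; sd is the standard
#'   error of the slope) or `"diff"` (mean and sd of successive
#'   differences).
#' @return `list(spacing_nm, sd_nm)`.
#' @export
estimate_spacing <- function(peaks, method = c("regression", "diff")) {
  method <- match.arg(method)
  if (is.null(peaks$z_nm) || nrow(peaks) < 3)
    swf_analysis_error("need >= 3 height-mapped peaks to estimate spacing")
  if (method == "regression") {
    fit <- stats::lm(z_nm ~ antinode_index, data = peaks)
    # exact antinode ladders give a perfect fit; the warning is expected
    sm <- suppressWarnings(summary(fit))
    list(spacing_nm = unname(stats::coef(fit)[2]),
         sd_nm = unname(sm$coefficients[2, 2]))
  } else {
    d <- diff(peaks$z_nm) / diff(peaks$antinode_index)
    list(spacing_nm = mean(d), sd_nm = stats::sd(d))
  }
}

#' Relative error of a measured spacing against the theoretical value
#'
#' @param spacing_nm Measured antinodal spacing (nm).
#' @param cfg An [optics_config()] giving the theoretical spacing
#'   \eqn{\lambda/2n}.
#' @return Relative error in percent,
#'   `|spacing - lambda/2n| / (lambda/2n) * 100`.
#' @export
spacing_relative_error <- function(spacing_nm, cfg) {
  th <- antinode_spacing(cfg)
  abs(spacing_nm - th) / th * 100
}

#' Estimate the moire envelope period from peak amplitudes
#'
#' The amplitudes of successive fringe peaks, taken as a function of their
#' height above the mirror, trace the beat envelope between the excitation
#' and emission standing-wave fields. Envelope maxima are detected (with a
#' prominence threshold relative to the largest amplitude, so an
#' unmodulated amplitude sequence raises an error) and refined with the
#' same bounded cubic-interpolation procedure as the fringe peaks; the
#' period is the mean height spacing of the refined maxima.
#'
#' @param peaks A `fringe_peaks` object with `z_nm` filled.
#' @param n Refractive index used to scale the height-domain period to the
#'   wavelength-like moire period `L = period * 2n`.
#' @param min_prominence Minimum envelope-maximum prominence as a fraction
#'   of the maximum amplitude.
#' @return `list(period_z_nm, L_nm, n_maxima)`.
#' @export
estimate_envelope_period <- function(peaks, n = 1, min_prominence = 0.1) {
  if (is.null(peaks$z_nm) || nrow(peaks) < 4)
    swf_analysis_error("need height-mapped peaks to trace the envelope")
  z <- peaks$z_nm; a <- peaks$amplitude
  lm <- local_maxima_prominence(a)
  keep <- lm$prom >= min_prominence * max(a)
  idx <- lm$i[keep]
  if (length(idx) < 2)
    swf_analysis_error(
      "fewer than 2 envelope maxima: amplitude modulation absent",
      "swf_no_envelope")
  ref <- refine_maxima(z, a, idx)
  period <- mean(diff(ref[, 1]))
  list(period_z_nm = period, L_nm = period * 2 * n,
       n_maxima = length(idx))
}

#' Pixel-wise image subtraction, clipped at zero
#'
#' @param a,b [fringe_image()]s on the same grid.
#' @return A [fringe_image()] of `pmax(a - b, 0)`; metadata records both
#'   parents' metadata.
#' @export
subtract_images <- function(a, b) {
  stopifnot(inherits(a, "fringe_image"), inherits(b, "fringe_image"))
  if (!all(dim(a$data) == dim(b$data)) || a$pixel_size_nm != b$pixel_size_nm)
    swf_config_error("images must share dimensions and pixel size",
                     field = "b")
  fringe_image(pmax(a$data - b$data, 0), a$pixel_size_nm,
               list(kind = "difference",
                    minuend = a$metadata, subtrahend = b$metadata))
}

#' Full fringe-analysis chain on a cap image
#'
#' Runs centre finding, azimuthal radial profiling, peak detection with
#' subpixel refinement, radius-to-height conversion and spacing estimation;
#' optionally also the moire-envelope period.
#'
#' @param img A [fringe_image()].
#' @param spec A [spherical_cap()] describing the specimen geometry.
#' @param cfg An [optics_config()].
#' @param bin_width_nm Radial bin width (default: one pixel).
#' @param min_prominence Peak prominence threshold (fraction of profile
#'   range).
#' @param envelope Also estimate the moire envelope period.
#' @param center_px Known centre (pixel units); found automatically when
#'   NULL.
#' @return A list report: `n_peaks`, `spacing_nm`, `spacing_sd_nm`,
#'   `theoretical_spacing_nm`, `rel_error_pct`, `center_px`, `peaks`,
#'   `profile`, and when requested `envelope_L_nm`, `envelope_period_z_nm`.
#' @export
analyze_fringe_image <- function(img, spec, cfg, bin_width_nm = NULL,
                                 min_prominence = 0.1, envelope = FALSE,
                                 center_px = NULL) {
  if (is.null(center_px)) center_px <- find_fringe_center(img)
  prof <- radial_profile(img, center_px, bin_width_nm)
  peaks <- detect_peaks(prof, min_prominence)
  peaks <- radii_to_heights(peaks, spec, cfg)
  sp <- estimate_spacing(peaks)
  rep <- list(n_peaks = nrow(peaks),
              spacing_nm = sp$spacing_nm,
              spacing_sd_nm = sp$sd_nm,
              theoretical_spacing_nm = antinode_spacing(cfg),
              rel_error_pct = spacing_relative_error(sp$spacing_nm, cfg),
              center_px = unname(center_px),
              peaks = peaks, profile = prof)
  if (envelope) {
    env <- estimate_envelope_period(peaks, n = cfg$refractive_index)
    rep$envelope_L_nm <- env$L_nm
    rep$envelope_period_z_nm <- env$period_z_nm
  }
  rep
}

#' Rank candidate base antinode indices by moire-envelope phase
#'
#' The beat envelope is phase-locked to the mirror (both standing waves
#' have a node there), so the observed peak-amplitude sequence should
#' follow \eqn{\cos^2(2\pi n z / L)}. Shifting the assumed base antinode
#' index shifts the predicted heights; the correlation between observed
#' amplitudes and the predicted envelope ranks the candidates, giving the
#' amplitude-based disambiguation of absolute fringe order.
#'
#' @param peaks A `fringe_peaks` object with `z_nm` and `antinode_index`.
#' @param cfg An [optics_config()] in a moire-bearing mode (detection
#'   centre set).
#' @param candidates Candidate base indices to score.
#' @return Data frame of `base_index` and correlation `score`, best first.
#' @export
rank_base_index <- function(peaks, cfg, candidates = 0:5) {
  stopifnot(inherits(cfg, "optics_config"))
  if (is.null(cfg$detection_center_nm))
    swf_config_error("cfg must carry a detection centre for the moire hint",
                     field = "detection_center_nm")
  L <- moire_period(cfg$excitation_nm, cfg$detection_center_nm)
  n <- cfg$refractive_index
  half <- axial_fwhm(cfg)
  scores <- vapply(candidates, function(b) {
    zb <- (2 * (peaks$antinode_index + b) + 1) * half
    stats::cor(peaks$amplitude, cos(2 * pi * n * zb / L)^2)
  }, numeric(1))
  out <- data.frame(base_index = candidates, score = scores)
  out[order(out$score, decreasing = TRUE), ]
}
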