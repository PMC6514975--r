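#' Full width at half maximum of a sampled profile
#'
#' Width between the two half-maximum crossings bracketing the global peak,
#' with linear interpolation between adjacent samples. The resolution metric
#' throughout: focal-spot size is the FWHM of the intensity profile through
#' the focus.
#'
#' @param positions 1-D coordinates along the profile, mm (ascending).
#' @param values non-negative intensity samples, same length.
#' @return width in mm.
#' @examples
#' x <- seq(-1, 1, 0.01)
#' fwhm(x, exp(-x^2 / (2 * 0.2^2)))  # 2*sqrt(2*log(2))*0.2 = 0.471
#' @export
fwhm <- function(positions, values) {
  stopifnot(length(positions) == length(values), length(values) >= 5)
  i0 <- which.max(values)
  half <- values[i0] / 2
  cross <- function(step) {
    i <- i0
    while (i + step >= 1 && i + step <= length(values) &&
           values[i + step] >= half) i <- i + step
    if (i + step < 1 || i + step > length(values))
      ra_stop(paste("half maximum not crossed inside the profile window",
                    "(truncated profile)"),
              "racingarray_profile_window")
    j <- i + step
    positions[i] + (half - values[i]) / (values[j] - values[i]) *
      (positions[j] - positions[i])
  }
  abs(cross(1L) - cross(-1L))
}

#' Intensity profile along a line through a synthesized field
#'
#' @param fit a [synthesize()] result.
#' @param center line centre, mm.
#' @param direction profile direction (3-vector).
#' @param half_length half profile length, mm.
#' @param spacing sample spacing, mm (0.02 mm keeps interpolation error well
#'   under the grid tolerance of the focal metrics).
#' @return list with offsets `s` (mm), `intensity` (W/cm^2) and complex
#'   `pressure`.
#' @export
beam_profile <- function(fit, center, direction, half_length = 1.5,
                         spacing = 0.02) {
  obs <- line_points(center, direction, half_length, spacing)
  fm <- predict(fit, obs, what = "field")
  list(s = obs$grid$s, intensity = fm$intensity, pressure = fm$pressure,
       direction = obs$grid$direction, center = center)
}

# peak-to-background ratio on a focal-plane map: maximum intensity outside
# exclusion discs of radius `exclude_mm` around each focus, relative to the
# in-focus peak
.background_ratio <- function(field, foci_xy, exclude_mm) {
  g <- field$obs$grid
  pts <- field$obs$points
  outside <- rep(TRUE, nrow(pts))
  for (i in seq_len(nrow(foci_xy))) {
    d2 <- (pts[, 1] - foci_xy[i, 1])^2 + (pts[, 2] - foci_xy[i, 2])^2
    outside <- outside & d2 > exclude_mm^2
  }
  if (!any(outside)) return(NA_real_)
  max(field$intensity[outside]) / max(field$intensity)
}

#' Single-focus resolution experiment
#'
#' Synthesizes one focus at the posterior retina (default (0, 0, -12) mm),
#' measures the lateral FWHM of the intensity profile along x at the focal
#' depth, and (optionally) renders the X-Y and X-Z plane intensity maps.
#' The off-focus background ratio (peak background intensity outside a
#' 2*FWHM disc, relative to the focal peak) quantifies the grating-lobe
#' noise that sparser tilings produce.
#'
#' @param spec preset label (`"type_a"` ... `"type_u"`), [array_spec()] or
#'   `cap_array`.
#' @param medium a [medium_spec()].
#' @param focus focus location, mm.
#' @param method solver, see [synthesize()].
#' @param profile_half_length,profile_spacing lateral profile geometry, mm.
#' @param render_planes also compute the two plane maps (slower).
#' @param plane_half_extent,plane_spacing plane-map geometry, mm.
#' @return list of class `resolution_report`: the fit, `fwhm_mm`, the
#'   profile, peak offset, and when rendered, `plane_xy`, `plane_xz` and
#'   `background_ratio`. The plane maps default to the +-6 mm retinal patch
#'   so the sparse tilings' grating lobes (which sit several mm off the
#'   focus) are inside the background window.
#' @export
single_focus_experiment <- function(spec = "type_i", medium = medium_spec(),
                                    focus = c(0, 0, -12),
                                    method = "weighted",
                                    profile_half_length = 1.5,
                                    profile_spacing = 0.02,
                                    render_planes = TRUE,
                                    plane_half_extent = 6,
                                    plane_spacing = 0.1) {
  fit <- synthesize(spec, make_target(focus), medium, method = method)
  prof <- beam_profile(fit, focus, c(1, 0, 0), profile_half_length,
                       profile_spacing)
  w <- fwhm(prof$s, prof$intensity)
  out <- list(fit = fit, focus = focus, fwhm_mm = w, profile = prof,
              profile_direction = c(1, 0, 0),
              peak_offset_mm = prof$s[which.max(prof$intensity)])
  if (render_planes) {
    gxy <- plane_grid("xy", center = focus[1:2], offset = focus[3],
                      half_extent = plane_half_extent,
                      spacing = plane_spacing)
    gxz <- plane_grid("xz", center = c(focus[1], focus[3]), offset = focus[2],
                      half_extent = plane_half_extent,
                      spacing = plane_spacing)
    out$plane_xy <- predict(fit, gxy, what = "field")
    out$plane_xz <- predict(fit, gxz, what = "field")
    out$background_ratio <- .background_ratio(out$plane_xy,
                                              matrix(focus[1:2], 1),
                                              2 * w)
  }
  class(out) <- "resolution_report"
  out
}

#' @export
print.resolution_report <- function(x, ...) {
  cat(sprintf("Resolution report ('%s'): FWHM = %.3f mm at (%g, %g, %g) mm\n",
              x$fit$geometry$spec$label, x$fwhm_mm, x$focus[1], x$focus[2],
              x$focus[3]))
  if (!is.null(x$background_ratio))
    cat(sprintf("  off-focus background ratio: %.4f\n", x$background_ratio))
  invisible(x)
}

#' Simultaneous multi-focus grid experiment
#'
#' Synthesizes an `n_side` x `n_side` grid of simultaneous foci at depth `z`
#' and reports the per-focus lateral FWHM (profile along x, windowed to half
#' the grid spacing so neighbouring spots do not leak into the estimate) and
#' the offset of each rendered intensity peak from its requested focus.
#'
#' @param spec array preset / spec / geometry.
#' @param n_side foci per side (2, 3 or 5 in the studied patterns).
#' @param spacing grid spacing, mm.
#' @param z focal depth, mm.
#' @param medium a [medium_spec()].
#' @param method solver.
#' @param profile_spacing profile sample spacing, mm.
#' @return list of class `multifocus_report` with per-focus `fwhm_mm`,
#'   `mean_fwhm_mm`, `peak_offset_mm` and the fit.
#' @export
multi_focus_experiment <- function(spec = "type_i", n_side = 3, spacing = 2,
                                   z = -12, medium = medium_spec(),
                                   method = "weighted",
                                   profile_spacing = 0.02) {
  foci <- focus_grid(n_side, spacing, z)
  fit <- synthesize(spec, make_target(foci), medium, method = method)
  half_win <- spacing / 2
  fws <- numeric(nrow(foci))
  offs <- numeric(nrow(foci))
  for (i in seq_len(nrow(foci))) {
    prof <- beam_profile(fit, foci[i, ], c(1, 0, 0), half_win,
                         profile_spacing)
    fws[i] <- fwhm(prof$s, prof$intensity)
    offs[i] <- abs(prof$s[which.max(prof$intensity)])
  }
  structure(list(fit = fit, foci = foci, fwhm_mm = fws,
                 mean_fwhm_mm = mean(fws), peak_offset_mm = offs),
            class = "multifocus_report")
}

#' @export
print.multifocus_report <- function(x, ...) {
  cat(sprintf(paste0("Multi-focus report ('%s'): %d foci, mean FWHM = %.3f ",
                     "mm, max peak offset = %.3f mm\n"),
              x$fit$geometry$spec$label, nrow(x$foci), x$mean_fwhm_mm,
              max(x$peak_offset_mm)))
  invisible(x)
}

#' The seven printed depth-scan foci
#'
#' Seven collinear points spanning depths z = -6 to -18 mm in the plane
#' x + y = 0, from (-6, 6, -6) to (6, -6, -18).
#'
#' @return 7 x 3 matrix, mm.
#' @export
depth_scan_foci <- function() {
  x <- seq(-6, 6, by = 2)
  cbind(x, -x, -12 - x)
}

#' Depth-scan experiment: seven simultaneous foci
#'
#' Synthesizes the seven printed foci simultaneously and measures each
#' spot's FWHM along the in-plane (x + y = 0) direction perpendicular to the
#' line through the points, (1, -1, 2)/sqrt(6). The profile window is half
#' the inter-focus spacing. Retinal tissue is not flat, so spot size as a
#' function of depth is the relevant robustness check for a curved target
#' surface.
#'
#' @param spec array preset / spec / geometry (the 512-element 5 MHz racing
#'   array by default).
#' @param medium a [medium_spec()].
#' @param method solver.
#' @param profile_spacing sample spacing, mm.
#' @return list of class `depth_scan_report` with the foci, per-point
#'   `fwhm_mm`, `peak_offset_mm`, the profile direction and the fit.
#' @export
depth_scan_experiment <- function(spec = "type_i", medium = medium_spec(),
                                  method = "weighted",
                                  profile_spacing = 0.02) {
  foci <- depth_scan_foci()
  fit <- synthesize(spec, make_target(foci), medium, method = method)
  dir <- c(1, -1, 2) / sqrt(6)
  half_win <- sqrt(sum((foci[2, ] - foci[1, ])^2)) / 2
  fws <- numeric(nrow(foci)); offs <- numeric(nrow(foci))
  for (i in seq_len(nrow(foci))) {
    prof <- beam_profile(fit, foci[i, ], dir, half_win, profile_spacing)
    fws[i] <- fwhm(prof$s, prof$intensity)
    offs[i] <- abs(prof$s[which.max(prof$intensity)])
  }
  structure(list(fit = fit, foci = foci, fwhm_mm = fws,
                 peak_offset_mm = offs, profile_direction = dir),
            class = "depth_scan_report")
}

#' @export
print.depth_scan_report <- function(x, ...) {
  cat(sprintf("Depth-scan report ('%s'):\n", x$fit$geometry$spec$label))
  for (i in seq_len(nrow(x$foci)))
    cat(sprintf("  (%+g, %+g, %+g) mm: FWHM = %.3f mm\n",
                x$foci[i, 1], x$foci[i, 2], x$foci[i, 3], x$fwhm_mm[i]))
  invisible(x)
}

#' Control points from a monochrome bitmap
#'
#' Converts the on-pixels of a small monochrome raster (e.g. character
#' patterns) into a centred grid of control points in a constant-z plane,
#' one focus per on-pixel with equal amplitudes. Bitmap row 1 is the top
#' row of the pattern (+y).
#'
#' @param bitmap 0/1 matrix (rows = image rows, top first).
#' @param pitch_mm pixel pitch, mm.
#' @param z plane depth, mm.
#' @param amplitude prescribed pressure, Pa.
#' @return a `target_pattern`.
#' @export
bitmap_target <- function(bitmap, pitch_mm = 1, z = -12, amplitude = 1) {
  bitmap <- as.matrix(bitmap)
  on <- which(bitmap != 0, arr.ind = TRUE)
  if (nrow(on) < 1)
    ra_stop("bitmap has no on-pixels", "racingarray_invalid_target")
  nr <- nrow(bitmap); nc <- ncol(bitmap)
  x <- (on[, 2] - (nc + 1) / 2) * pitch_mm
  y <- ((nr + 1) / 2 - on[, 1]) * pitch_mm
  make_target(cbind(x, y, z), amplitude)
}

#' Acoustic-output safety report
#'
#' Scales a rendered field so the focal (peak) time-averaged intensity
#' equals `focal_intensity_W_cm2` and reports the fraction of grid points
#' above the regulatory and physiological thresholds: 50 mW/cm^2 (the
#' ophthalmic limit), 720 mW/cm^2 (the general-tissue limit) and 0.25
#' W/cm^2 (the neuromodulation threshold).
#'
#' @param field a `field_map`.
#' @param focal_intensity_W_cm2 calibrated peak intensity, W/cm^2.
#' @return list with peak intensity, threshold fractions and flags.
#' @export
safety_report <- function(field, focal_intensity_W_cm2) {
  stopifnot(inherits(field, "field_map"))
  peak <- max(field$intensity)
  I <- if (peak > 0) field$intensity / peak * focal_intensity_W_cm2
       else field$intensity
  thresholds <- c(eye_50mW = 0.050, tissue_720mW = 0.720,
                  neuromod_250mW = 0.250)
  frac <- vapply(thresholds, function(th) mean(I > th), numeric(1))
  list(peak_I_W_cm2 = max(I), thresholds_W_cm2 = thresholds,
       fraction_above = frac, flagged = frac > 0)
}

#' Compare two element counts of the same aperture
#'
#' Synthesizes the same single focus with two configurations (by default
#' the 512- and 1024-element 5 MHz racing arrays) and quantifies how alike
#' the fields are: (i) the maximum difference of the peak-normalized
#' lateral intensity profiles through the focus, inside the focal zone
#' (within `zone_fwhm_mult` lateral FWHMs); and (ii) the fraction of the
#' X-Z difference field's energy that lies outside that zone, i.e. how
#' much of the disagreement is peripheral.
#'
#' @param spec_a,spec_b the two configurations.
#' @param focus common focus, mm.
#' @param medium a [medium_spec()].
#' @param half_extent,spacing X-Z map geometry, mm.
#' @param zone_fwhm_mult focal-zone radius in units of the lateral FWHM.
#' @param method solver.
#' @return list with `focal_zone_max_diff` (relative, from the lateral
#'   profiles), `outside_energy_fraction` (from the X-Z difference map),
#'   per-config FWHMs and the two normalized fields.
#' @export
compare_element_counts <- function(spec_a = "type_i", spec_b = "type_m",
                                   focus = c(0, 0, -12),
                                   medium = medium_spec(),
                                   half_extent = 3, spacing = 0.05,
                                   zone_fwhm_mult = 2, method = "weighted") {
  run <- function(spec) {
    fit <- synthesize(spec, make_target(focus), medium, method = method)
    prof <- beam_profile(fit, focus, c(1, 0, 0), 1.5, 0.02)
    g <- plane_grid("xz", center = c(focus[1], focus[3]), offset = focus[2],
                    half_extent = half_extent, spacing = spacing)
    fm <- predict(fit, g, what = "field")
    list(fit = fit, fwhm = fwhm(prof$s, prof$intensity), prof = prof,
         field = fm)
  }
  a <- run(spec_a); b <- run(spec_b)
  zone_r <- zone_fwhm_mult * max(a$fwhm, b$fwhm)
  in_zone <- abs(a$prof$s) <= zone_r
  dprof <- abs(a$prof$intensity / max(a$prof$intensity) -
                 b$prof$intensity / max(b$prof$intensity))
  Ia <- a$field$intensity / max(a$field$intensity)
  Ib <- b$field$intensity / max(b$field$intensity)
  pts <- a$field$obs$points
  r2 <- (pts[, 1] - focus[1])^2 + (pts[, 3] - focus[3])^2
  zone <- r2 <= zone_r^2
  d <- abs(Ia - Ib)
  list(fwhm_mm = c(a = a$fwhm, b = b$fwhm),
       focal_zone_max_diff = max(dprof[in_zone]),
       outside_energy_fraction = sum(d[!zone]^2) / sum(d^2),
       field_a = a$field, field_b = b$field, zone = zone)
}
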