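#' Parametric spherical-cap array specification
#'
#' Describes an annular ("racing") or full-cap array of rectangular-ish
#' elements tiled on a spherical cap of curvature radius `roc_mm`. The inner
#' and outer diameters are the transverse (projected) diameters of the annular
#' band; an inner diameter of 0 gives a full cap starting at the apex. The
#' nominal element size is `element_width_mm` along the azimuthal direction
#' and `element_height_mm` along the polar (ring-to-ring) direction.
#'
#' @param f drive frequency in Hz.
#' @param n_elements number of array elements (>= 1).
#' @param inner_diameter_mm inner aperture diameter, mm (0 for a full cap).
#' @param outer_diameter_mm outer aperture diameter, mm.
#' @param element_width_mm nominal azimuthal element width, mm.
#' @param element_height_mm nominal polar element height, mm.
#' @param roc_mm radius of curvature of the cap, mm (12 mm fits the adult
#'   eyeball).
#' @param label free-form configuration label.
#' @return an object of class `array_spec`.
#' @seealso [preset_array()] for the six shipped configurations,
#'   [build_array()] to realize the element tiling.
#' @export
array_spec <- function(f, n_elements, inner_diameter_mm, outer_diameter_mm,
                       element_width_mm, element_height_mm, roc_mm = 12,
                       label = "custom") {
  num1 <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  if (!num1(f) || f <= 0)
    ra_stop("frequency f must be a single positive number (Hz)",
            "racingarray_invalid_spec")
  if (!num1(n_elements) || n_elements < 1 || n_elements != round(n_elements))
    ra_stop("n_elements must be a positive integer",
            "racingarray_invalid_spec")
  if (!num1(roc_mm) || roc_mm <= 0)
    ra_stop("roc_mm must be positive", "racingarray_invalid_spec")
  if (!num1(inner_diameter_mm) || !num1(outer_diameter_mm) ||
      inner_diameter_mm < 0 || inner_diameter_mm >= outer_diameter_mm ||
      outer_diameter_mm > 2 * roc_mm)
    ra_stop("diameters must satisfy 0 <= inner < outer <= 2*roc",
            "racingarray_invalid_spec")
  if (!num1(element_width_mm) || element_width_mm <= 0 ||
      !num1(element_height_mm) || element_height_mm <= 0)
    ra_stop("nominal element dimensions must be positive",
            "racingarray_invalid_spec")
  structure(list(f = as.numeric(f), n_elements = as.integer(n_elements),
                 inner_diameter_mm = as.numeric(inner_diameter_mm),
                 outer_diameter_mm = as.numeric(outer_diameter_mm),
                 element_width_mm = as.numeric(element_width_mm),
                 element_height_mm = as.numeric(element_height_mm),
                 roc_mm = as.numeric(roc_mm), label = label),
            class = "array_spec")
}

# the six simulated configurations (frequency, element count, nominal element
# size, inner/outer aperture diameters); curvature radius 12 mm throughout
.preset_table <- list(
  type_a = list(f = 2.5e6, n = 256L,  w = 0.61, h = 0.58, din = 0,  dout = 14),
  type_e = list(f = 5e6,   n = 256L,  w = 0.28, h = 0.94, din = 10, dout = 18),
  type_i = list(f = 5e6,   n = 512L,  w = 0.37, h = 0.50, din = 10, dout = 18),
  type_m = list(f = 5e6,   n = 1024L, w = 0.22, h = 0.30, din = 10, dout = 18),
  type_q = list(f = 10e6,  n = 512L,  w = 0.37, h = 0.50, din = 10, dout = 18),
  type_u = list(f = 10e6,  n = 1024L, w = 0.22, h = 0.30, din = 10, dout = 18)
)

#' Shipped array configurations
#'
#' Named presets `"type_a"` ... `"type_u"` covering the six studied designs:
#' the 2.5 MHz / 256-element full cap (`type_a`, the traditional contact-lens
#' design covering the pupil) and the 5/10 MHz annular racing arrays with
#' 256, 512 or 1024 elements. Short labels `"a"`, `"e"`, `"i"`, `"m"`, `"q"`,
#' `"u"` are accepted.
#'
#' @param name preset name or short label.
#' @return an [array_spec()].
#' @examples
#' preset_array("type_i") # 5 MHz, 512 elements, 10-18 mm annulus
#' @export
preset_array <- function(name) {
  key <- tolower(as.character(name)[1])
  if (key %in% c("a", "e", "i", "m", "q", "u")) key <- paste0("type_", key)
  if (!key %in% names(.preset_table))
    ra_stop(sprintf("unknown array preset '%s' (use type_a/e/i/m/q/u)", name),
            "racingarray_invalid_spec")
  p <- .preset_table[[key]]
  array_spec(f = p$f, n_elements = p$n, inner_diameter_mm = p$din,
             outer_diameter_mm = p$dout, element_width_mm = p$w,
             element_height_mm = p$h, roc_mm = 12, label = key)
}

#' @export
print.array_spec <- function(x, ...) {
  cat(sprintf(paste0("Spherical-cap array spec '%s': %g MHz, %d elements,\n",
                     "  aperture %g-%g mm (diameter), R = %g mm, nominal ",
                     "element %g x %g mm\n"),
              x$label, x$f / 1e6, x$n_elements, x$inner_diameter_mm,
              x$outer_diameter_mm, x$roc_mm, x$element_width_mm,
              x$element_height_mm))
  invisible(x)
}

# polar band [phi_in, phi_out] implied by the projected aperture diameters
.band_angles <- function(spec) {
  R <- spec$roc_mm
  c(asin(spec$inner_diameter_mm / 2 / R),
    asin(spec$outer_diameter_mm / 2 / R))
}

#' Spherical band area implied by an array spec
#'
#' Area of the spherical zone between the inner and outer aperture
#' diameters, `2*pi*R^2*(cos(phi_in) - cos(phi_out))`, in mm^2.
#'
#' @param spec an [array_spec()].
#' @export
band_area_mm2 <- function(spec) {
  ang <- .band_angles(spec)
  2 * pi * spec$roc_mm^2 * (cos(ang[1]) - cos(ang[2]))
}

#' Tile a racing-array spec into concrete elements
#'
#' Splits the polar band into rings of height close to the nominal element
#' height, allocates elements to rings proportionally to ring circumference
#' (largest-remainder rounding so counts sum to exactly `n_elements`), and
#' centres each element at its ring's polar angle with the nominal angular
#' extents. Remaining band area is kerf/gap, which is how the studied designs
#' reach sub-unity fill factors.
#'
#' @param spec an [array_spec()] or preset name.
#' @return an object of class `cap_array`: the spec plus a data frame of
#'   elements with centres (mm, on the sphere), inward unit normals, angular
#'   extents (rad) and exact areas (mm^2).
#' @examples
#' geom <- build_array(preset_array("type_i"))
#' nrow(geom$elements) # 512
#' @export
build_array <- function(spec) {
  if (is.character(spec)) spec <- preset_array(spec)
  stopifnot(inherits(spec, "array_spec"))
  R <- spec$roc_mm
  ang <- .band_angles(spec)
  band_h <- R * (ang[2] - ang[1])
  n_rings <- max(1L, min(as.integer(round(band_h / spec$element_height_mm)),
                         spec$n_elements))
  pitch_phi <- (ang[2] - ang[1]) / n_rings
  phi_c <- ang[1] + (seq_len(n_rings) - 0.5) * pitch_phi

  # elements per ring proportional to circumference, exact total
  wgt <- sin(phi_c)
  ideal <- spec$n_elements * wgt / sum(wgt)
  n_k <- floor(ideal)
  rem <- spec$n_elements - sum(n_k)
  if (rem > 0) {
    ord <- order(ideal - n_k, decreasing = TRUE)
    n_k[ord[seq_len(rem)]] <- n_k[ord[seq_len(rem)]] + 1
  }
  # every ring keeps at least one element (take from the fullest ring)
  while (any(n_k == 0)) {
    i0 <- which(n_k == 0)[1]
    imax <- which.max(n_k)
    n_k[i0] <- 1L
    n_k[imax] <- n_k[imax] - 1L
  }

  d_phi <- min(spec$element_height_mm / R, pitch_phi)
  rows <- vector("list", n_rings)
  for (k in seq_len(n_rings)) {
    circ <- 2 * pi * R * sin(phi_c[k])
    if (n_k[k] * spec$element_width_mm > circ * (1 + 1e-12))
      ra_stop(sprintf(paste0("infeasible tiling: ring %d (phi = %.3f rad, ",
                             "circumference %.2f mm) cannot hold %d elements ",
                             "of width %g mm"),
                      k, phi_c[k], circ, n_k[k], spec$element_width_mm),
              "racingarray_infeasible_tiling")
    d_theta <- spec$element_width_mm / (R * sin(phi_c[k]))
    theta_c <- 2 * pi * (seq_len(n_k[k]) - 1) / n_k[k]
    phi1 <- phi_c[k] - d_phi / 2
    phi2 <- phi_c[k] + d_phi / 2
    rows[[k]] <- data.frame(
      ring = k,
      phi1 = phi1, phi2 = phi2,
      theta1 = theta_c - d_theta / 2, theta2 = theta_c + d_theta / 2,
      cx = R * sin(phi_c[k]) * cos(theta_c),
      cy = R * sin(phi_c[k]) * sin(theta_c),
      cz = R * cos(phi_c[k]),
      area_mm2 = R^2 * (cos(phi1) - cos(phi2)) * d_theta
    )
  }
  el <- do.call(rbind, rows)
  el <- cbind(index = seq_len(nrow(el)), el)
  el$nx <- -el$cx / R
  el$ny <- -el$cy / R
  el$nz <- -el$cz / R
  structure(list(spec = spec, elements = el, n_rings = n_rings,
                 ring_pitch_phi = pitch_phi, band_angles = ang,
                 coordinate_convention = paste(
                   "eyeball sphere of radius roc_mm centred at the origin;",
                   "array band around the +z apex; posterior retina at",
                   "(0, 0, -roc_mm) mm")),
            class = "cap_array")
}

#' @export
print.cap_array <- function(x, ...) {
  rs <- realized_element_size(x)
  cat(sprintf(paste0("Spherical-cap array '%s': %d elements in %d rings,\n",
                     "  aperture %g-%g mm, R = %g mm, f = %g MHz\n",
                     "  realized element size %.3f x %.3f mm (mean),",
                     " active area %.1f mm^2\n"),
              x$spec$label, nrow(x$elements), x$n_rings,
              x$spec$inner_diameter_mm, x$spec$outer_diameter_mm,
              x$spec$roc_mm, x$spec$f / 1e6, rs["width"], rs["height"],
              sum(x$elements$area_mm2)))
  invisible(x)
}

#' @export
summary.cap_array <- function(object, ...) {
  el <- object$elements
  per_ring <- table(el$ring)
  cat(sprintf("Array '%s': %d elements, %d rings (%s per ring)\n",
              object$spec$label, nrow(el), object$n_rings,
              paste(range(per_ring), collapse = "-")))
  print(preset_aperture_summary(object))
  invisible(object)
}

preset_aperture_summary <- function(geom) {
  data.frame(active_area_mm2 = sum(geom$elements$area_mm2),
             band_area_mm2 = band_area_mm2(geom$spec),
             fill_factor = sum(geom$elements$area_mm2) /
               band_area_mm2(geom$spec))
}

#' @export
plot.cap_array <- function(x, ...) {
  el <- x$elements
  graphics::plot(el$cx, el$cy, asp = 1, pch = 16,
                 cex = 0.4, xlab = "x (mm)", ylab = "y (mm)",
                 main = sprintf("%s: element centres (top view)",
                                x$spec$label), ...)
  invisible(x)
}

#' Mean realized element arc dimensions
#'
#' @param geometry a [build_array()] result.
#' @return named vector `c(width=, height=)` of mean azimuthal and polar arc
#'   lengths in mm.
#' @export
realized_element_size <- function(geometry) {
  el <- geometry$elements
  R <- geometry$spec$roc_mm
  phic <- (el$phi1 + el$phi2) / 2
  c(width = mean(R * sin(phic) * (el$theta2 - el$theta1)),
    height = mean(R * (el$phi2 - el$phi1)))
}

#' Discretize array elements into weighted quadrature source points
#'
#' Subdivides each element in (phi, theta) so that arc spacing does not
#' exceed lambda/`samples_per_wavelength`, placing one source point at each
#' sub-cell's angular midpoint. The sub-cell weight is the exact spherical
#' area `R^2 (cos phi_a - cos phi_b) dtheta`, i.e. `R^2 sin(phi~) dphi dtheta`
#' with `sin(phi~)` the cell-mean value, so per-element weights sum exactly
#' to the element area.
#'
#' @param geometry a `cap_array`.
#' @param medium a [medium_spec()].
#' @param samples_per_wavelength source points per wavelength (>= 2;
#'   default 4, which holds focal pressures to a fraction of a percent).
#' @param f frequency in Hz; defaults to the array spec's frequency.
#' @return object of class `source_quadrature`: matrix `points` (S x 3, mm),
#'   vector `weights` (mm^2) and integer `element` index per source point.
#' @export
element_quadrature <- function(geometry, medium,
                               samples_per_wavelength = 4,
                               f = geometry$spec$f) {
  stopifnot(inherits(geometry, "cap_array"), inherits(medium, "medium_spec"))
  if (samples_per_wavelength < 2)
    ra_stop("samples_per_wavelength must be >= 2",
            "racingarray_invalid_quadrature")
  lam <- wavelength_mm(medium, f)  # errors on non-positive wavelength inputs
  dmax <- lam / samples_per_wavelength
  R <- geometry$spec$roc_mm
  el <- geometry$elements
  out <- vector("list", nrow(el))
  for (i in seq_len(nrow(el))) {
    p1 <- el$phi1[i]; p2 <- el$phi2[i]
    t1 <- el$theta1[i]; t2 <- el$theta2[i]
    phic <- (p1 + p2) / 2
    n_phi <- max(1L, ceiling(R * (p2 - p1) / dmax))
    n_theta <- max(1L, ceiling(R * sin(phic) * (t2 - t1) / dmax))
    pe <- seq(p1, p2, length.out = n_phi + 1)
    te <- t1 + (seq_len(n_theta) - 0.5) * (t2 - t1) / n_theta
    dth <- (t2 - t1) / n_theta
    phim <- (pe[-1] + pe[-(n_phi + 1)]) / 2
    wphi <- R^2 * (cos(pe[-(n_phi + 1)]) - cos(pe[-1]))  # exact zone areas
    P <- rep(phim, times = n_theta)
    TT <- rep(te, each = n_phi)
    W <- rep(wphi, times = n_theta) * dth
    out[[i]] <- cbind(R * sin(P) * cos(TT), R * sin(P) * sin(TT),
                      R * cos(P), W, i)
  }
  m <- do.call(rbind, out)
  structure(list(points = unname(m[, 1:3, drop = FALSE]),
                 weights = unname(m[, 4]),
                 element = as.integer(m[, 5]), n_elements = nrow(el),
                 samples_per_wavelength = samples_per_wavelength,
                 roc_mm = R, f = f),
            class = "source_quadrature")
}

#' @export
print.source_quadrature <- function(x, ...) {
  cat(sprintf(paste0("Source quadrature: %d points over %d elements ",
                     "(%.1f per element), %g samples/wavelength\n"),
              nrow(x$points), x$n_elements, nrow(x$points) / x$n_elements,
              x$samples_per_wavelength))
  invisible(x)
}

#' Aperture, fill-factor and pitch report
#'
#' Summarises the realized tiling: total active area, spherical band area,
#' fill factor, per-ring centre-to-centre azimuthal pitch, and the maximum
#' pitch relative to the wavelength. Pitch/wavelength above 1 signals that
#' grating lobes are possible under beam steering.
#'
#' @param geometry a `cap_array`.
#' @param medium a [medium_spec()] (default water-like).
#' @param f frequency in Hz (defaults to the spec's).
#' @return list with `active_area_mm2`, `band_area_mm2`, `fill_factor`,
#'   per-ring data frame `rings` (count, arc pitch mm) and `max_pitch_ratio`
#'   (max pitch / lambda).
#' @export
aperture_report <- function(geometry, medium = medium_spec(),
                            f = geometry$spec$f) {
  stopifnot(inherits(geometry, "cap_array"))
  el <- geometry$elements
  R <- geometry$spec$roc_mm
  lam <- wavelength_mm(medium, f)
  rings <- do.call(rbind, lapply(split(el, el$ring), function(d) {
    phic <- (d$phi1[1] + d$phi2[1]) / 2
    data.frame(ring = d$ring[1], n = nrow(d), phi = phic,
               pitch_mm = 2 * pi * R * sin(phic) / nrow(d))
  }))
  list(active_area_mm2 = sum(el$area_mm2),
       band_area_mm2 = band_area_mm2(geometry$spec),
       fill_factor = sum(el$area_mm2) / band_area_mm2(geometry$spec),
       rings = rings,
       wavelength_mm = lam,
       max_pitch_ratio = max(rings$pitch_mm) / lam)
}

#' Element count needed for wavelength-pitch tiling
#'
#' Number of lambda x lambda elements required to tile the spec's spherical
#' band (band area / lambda^2, rounded up). Keeping the pitch at one
#' wavelength suppresses grating lobes but quickly becomes infeasible at
#' high frequency: the 10-18 mm racing band needs thousands of elements at
#' 10 MHz.
#'
#' @param spec an [array_spec()], preset name, or plain list with fields
#'   `f`, `inner_diameter_mm`, `outer_diameter_mm`, `roc_mm` (a plain list
#'   admits the degenerate inner == outer band, which needs 0 elements).
#' @param medium a [medium_spec()].
#' @return integer element count (0 for a degenerate band).
#' @export
required_element_count <- function(spec, medium = medium_spec()) {
  if (is.character(spec)) spec <- preset_array(spec)
  lam <- wavelength_mm(medium, spec$f)
  area <- band_area_mm2(spec)
  if (area <= 0) return(0L)
  as.integer(ceiling(area / lam^2))
}

#' Export element geometry as CSV
#'
#' Writes element index, centre x/y/z (mm), inward normal, angular extents
#' (rad) and area (mm^2).
#'
#' @param geometry a `cap_array`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_geometry_csv <- function(geometry, path) {
  stopifnot(inherits(geometry, "cap_array"))
  utils::write.csv(geometry$elements, path, row.names = FALSE)
  invisible(path)
}
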