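#' Observation point sets and grids
#'
#' `observation_points()` wraps an M x 3 matrix of field points (mm).
#' `plane_grid()` builds a regular grid on an axis-aligned plane and records
#' the descriptor needed to reshape field values back into an image.
#' `line_points()` samples a straight line for beam profiles.
#'
#' @param points M x 3 numeric matrix of coordinates in mm.
#' @return an `observation_set`: the points plus an optional grid descriptor.
#' @export
observation_points <- function(points) {
  points <- as.matrix(points)
  if (ncol(points) != 3 || nrow(points) < 1 || !all(is.finite(points)))
    ra_stop("observation points must be a finite M x 3 matrix (mm)",
            "racingarray_invalid_observation")
  structure(list(points = points, grid = NULL), class = "observation_set")
}

#' @param plane `"xy"` (constant z) or `"xz"` (constant y).
#' @param center plane-centre coordinates along the two in-plane axes, mm.
#' @param offset the constant third coordinate, mm.
#' @param half_extent half-width of the square grid, mm.
#' @param spacing grid spacing, mm.
#' @rdname observation_points
#' @export
plane_grid <- function(plane = c("xy", "xz"), center = c(0, 0), offset,
                       half_extent = 3, spacing = 0.05) {
  plane <- match.arg(plane)
  a <- seq(center[1] - half_extent, center[1] + half_extent, by = spacing)
  b <- seq(center[2] - half_extent, center[2] + half_extent, by = spacing)
  g <- expand.grid(a = a, b = b)
  pts <- switch(plane,
                xy = cbind(g$a, g$b, offset),
                xz = cbind(g$a, offset, g$b))
  obs <- observation_points(pts)
  obs$grid <- list(plane = plane, axis1 = a, axis2 = b, offset = offset,
                   spacing = spacing)
  obs
}

#' @param center line centre (3-vector, mm).
#' @param direction line direction (3-vector, normalized internally).
#' @param half_length profile half-length, mm.
#' @rdname observation_points
#' @export
line_points <- function(center, direction, half_length = 1.5,
                        spacing = 0.02) {
  direction <- direction / sqrt(sum(direction^2))
  s <- seq(-half_length, half_length, by = spacing)
  obs <- observation_points(outer(s, direction) +
                              matrix(center, length(s), 3, byrow = TRUE))
  obs$grid <- list(plane = "line", s = s, center = center,
                   direction = direction, spacing = spacing)
  obs
}

.as_obs <- function(obs) {
  if (inherits(obs, "observation_set")) return(obs)
  observation_points(obs)
}

# guard shared by operator/field builders: Rayleigh kernel is singular on the
# source surface
.check_standoff <- function(quad, obs, lam_mm) {
  dmin <- rs_min_dist_cpp(obs$points, quad$points)
  if (dmin <= lam_mm / 10)
    ra_stop(sprintf(paste0("near-singular kernel: observation point within ",
                           "lambda/10 of the source surface (min distance ",
                           "%.4g mm, lambda %.4g mm)"), dmin, lam_mm),
            "racingarray_near_singular_kernel")
  invisible(dmin)
}

#' Rayleigh-Sommerfeld forward propagation operator
#'
#' Builds the complex M x N transfer matrix H mapping per-element normal
#' velocity excitations (m/s) to time-harmonic pressure amplitudes (Pa) at M
#' observation points:
#' `H[m, n] = (j rho c k / 2 pi) * sum_q exp(-j k r_mq) / r_mq * dS_q`
#' summed over the n-th element's quadrature points, with `k = 2 pi f / c`.
#' The `exp(j omega t)` factor is dropped (amplitude convention).
#'
#' @param quadrature a [element_quadrature()] result.
#' @param obs observation points (matrix or `observation_set`), mm.
#' @param medium a [medium_spec()].
#' @param f frequency in Hz (defaults to the quadrature's).
#' @return a `propagation_operator`: complex matrix `H` plus the medium,
#'   frequency and quadrature identity used to build it.
#' @export
forward_operator <- function(quadrature, obs, medium = medium_spec(),
                             f = quadrature$f) {
  stopifnot(inherits(quadrature, "source_quadrature"),
            inherits(medium, "medium_spec"))
  obs <- .as_obs(obs)
  lam <- wavelength_mm(medium, f)
  .check_standoff(quadrature, obs, lam)
  k <- 2 * pi * f / medium$sound_speed            # rad/m
  amp <- medium$density * medium$sound_speed * k / (2 * pi)
  H <- rs_operator_cpp(obs$points * 1e-3, quadrature$points * 1e-3,
                       quadrature$weights * 1e-6,
                       quadrature$element - 1L, quadrature$n_elements,
                       k, amp)
  structure(list(H = H, medium = medium, f = f, obs = obs,
                 n_elements = quadrature$n_elements,
                 samples_per_wavelength = quadrature$samples_per_wavelength),
            class = "propagation_operator")
}

#' @export
print.propagation_operator <- function(x, ...) {
  cat(sprintf(paste0("Forward propagation operator: %d observation points x ",
                     "%d elements, f = %g MHz\n"),
              nrow(x$H), ncol(x$H), x$f / 1e6))
  invisible(x)
}

#' Pressure field for a given excitation
#'
#' Evaluates `p = H U` by streamed accumulation over source points, without
#' materializing H (memory stays bounded for large grids). Identical to an
#' explicit `H %*% U` to machine precision.
#'
#' @param quadrature a [element_quadrature()] result.
#' @param U complex excitation vector, one entry per element (normal surface
#'   velocity, m/s).
#' @param obs observation points (matrix or `observation_set`), mm.
#' @param medium a [medium_spec()].
#' @param f frequency in Hz.
#' @param block number of observation points per streamed block.
#' @return a `field_map` with complex `pressure` (Pa) and `intensity`
#'   (W/cm^2) per point.
#' @export
pressure_field <- function(quadrature, U, obs, medium = medium_spec(),
                           f = quadrature$f, block = 4096L) {
  stopifnot(inherits(quadrature, "source_quadrature"))
  if (length(U) != quadrature$n_elements)
    ra_stop("length(U) must equal the number of elements",
            "racingarray_invalid_excitation")
  obs <- .as_obs(obs)
  lam <- wavelength_mm(medium, f)
  .check_standoff(quadrature, obs, lam)
  k <- 2 * pi * f / medium$sound_speed
  amp <- medium$density * medium$sound_speed * k / (2 * pi)
  wu <- quadrature$weights * 1e-6 * as.complex(U)[quadrature$element]
  M <- nrow(obs$points)
  p <- complex(M)
  src <- quadrature$points * 1e-3
  for (i0 in seq(1L, M, by = block)) {
    i1 <- min(i0 + block - 1L, M)
    p[i0:i1] <- rs_field_cpp(obs$points[i0:i1, , drop = FALSE] * 1e-3,
                             src, wu, k, amp)
  }
  field_map(obs, p, medium)
}

#' Assemble a field map from pressures
#'
#' @param obs an `observation_set`.
#' @param pressure complex pressure amplitudes (Pa).
#' @param medium a [medium_spec()].
#' @return a `field_map`.
#' @export
field_map <- function(obs, pressure, medium) {
  obs <- .as_obs(obs)
  structure(list(obs = obs, pressure = pressure,
                 intensity = intensity_W_cm2(pressure, medium),
                 medium = medium),
            class = "field_map")
}

#' Time-averaged intensity from complex pressure
#'
#' Spatial-peak time-averaged (CW) intensity `I = p p* / (2 rho c)`,
#' converted from W/m^2 to W/cm^2.
#'
#' @param pressure complex pressure amplitude(s), Pa.
#' @param medium a [medium_spec()].
#' @return intensity in W/cm^2 (same shape as `pressure`).
#' @export
intensity_W_cm2 <- function(pressure, medium) {
  stopifnot(inherits(medium, "medium_spec"))
  Re(pressure * Conj(pressure)) /
    (2 * medium$density * medium$sound_speed) * 1e-4
}

#' @export
print.field_map <- function(x, ...) {
  cat(sprintf(paste0("Field map: %d points, peak |p| = %.4g Pa, ",
                     "peak intensity = %.4g W/cm^2\n"),
              length(x$pressure), max(Mod(x$pressure)), max(x$intensity)))
  invisible(x)
}

#' Reshape a plane-grid field map into an image matrix
#'
#' @param field a `field_map` built on a [plane_grid()].
#' @param what `"intensity"` or `"pressure"` (modulus).
#' @return list with `axis1`, `axis2` and matrix `z`.
#' @export
field_image <- function(field, what = c("intensity", "pressure")) {
  what <- match.arg(what)
  g <- field$obs$grid
  if (is.null(g) || identical(g$plane, "line"))
    ra_stop("field_image needs a plane-grid field map",
            "racingarray_invalid_observation")
  v <- if (what == "intensity") field$intensity else Mod(field$pressure)
  list(axis1 = g$axis1, axis2 = g$axis2,
       z = matrix(v, nrow = length(g$axis1)))
}

#' @export
plot.field_map <- function(x, what = "intensity", ...) {
  im <- field_image(x, what)
  graphics::image(im$axis1, im$axis2, im$z, col = grDevices::hcl.colors(64),
                  xlab = "axis 1 (mm)", ylab = "axis 2 (mm)",
                  main = sprintf("%s (%s)", what,
                                 if (what == "intensity") "W/cm^2" else "Pa"),
                  ...)
  invisible(x)
}

#' Closed-form focal pressure for uniform in-phase drive
#'
#' At the cap's centre of curvature every source path has length R, so the
#' Rayleigh integral collapses to `|p| = rho c k u S / (2 pi R)` with S the
#' total active element area. Serves as an independent oracle for the
#' numerical quadrature.
#'
#' @param geometry a `cap_array`.
#' @param medium a [medium_spec()].
#' @param f frequency, Hz.
#' @param u uniform drive amplitude (normal velocity, m/s).
#' @return pressure magnitude in Pa.
#' @export
analytic_focus_pressure <- function(geometry, medium = medium_spec(),
                                    f = geometry$spec$f, u = 1) {
  stopifnot(inherits(geometry, "cap_array"))
  k <- 2 * pi * f / medium$sound_speed
  S <- sum(geometry$elements$area_mm2) * 1e-6      # m^2
  R <- geometry$spec$roc_mm * 1e-3                 # m
  medium$density * medium$sound_speed * k * u * S / (2 * pi * R)
}
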