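#' Acoustic medium specification
#'
#' Homogeneous propagation medium for the eye's water path. Defaults are a
#' water-like vitreous at body-ish temperature: c = 1500 m/s, rho = 1000
#' kg/m^3. Absorption is deliberately not modelled: the annular aperture
#' exists precisely so the beam path avoids the strongly absorbing lens.
#'
#' @param sound_speed speed of sound in m/s.
#' @param density mass density in kg/m^3.
#' @return an object of class `medium_spec`.
#' @examples
#' water <- medium_spec()
#' wavelength_mm(water, 5e6) # 0.3 mm at 5 MHz
#' @export
medium_spec <- function(sound_speed = 1500, density = 1000) {
  if (!is.numeric(sound_speed) || length(sound_speed) != 1 ||
      !is.finite(sound_speed) || sound_speed <= 0)
    ra_stop("sound_speed must be a single positive number",
            "racingarray_invalid_medium")
  if (!is.numeric(density) || length(density) != 1 ||
      !is.finite(density) || density <= 0)
    ra_stop("density must be a single positive number",
            "racingarray_invalid_medium")
  structure(list(sound_speed = as.numeric(sound_speed),
                 density = as.numeric(density)),
            class = "medium_spec")
}

#' @export
print.medium_spec <- function(x, ...) {
  cat(sprintf("Acoustic medium: c = %g m/s, rho = %g kg/m^3\n",
              x$sound_speed, x$density))
  invisible(x)
}

#' Acoustic wavelength in millimetres
#'
#' @param medium a [medium_spec()].
#' @param f drive frequency in Hz.
#' @return wavelength c/f, in mm.
#' @export
wavelength_mm <- function(medium, f) {
  stopifnot(inherits(medium, "medium_spec"))
  if (!is.numeric(f) || length(f) != 1 || !is.finite(f) || f <= 0)
    ra_stop("frequency must be a single positive number (Hz)",
            "racingarray_invalid_medium")
  medium$sound_speed / f * 1e3
}
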