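#' Prescribed pressure pattern at control points
#'
#' Builds a target of equal-magnitude, zero-phase pressures at the given
#' focus points. Control-point phases are left at zero deliberately: phase
#' optimization across foci is out of scope, and equal zero-phase targets
#' are what the pattern-synthesis pseudoinverse expects.
#'
#' @param points M x 3 matrix (or list of 3-vectors) of focus coordinates, mm.
#' @param amplitude prescribed pressure magnitude at every focus, Pa.
#' @return a `target_pattern` with `points` and complex `pressure`.
#' @examples
#' make_target(c(0, 0, -12))            # single posterior-retina focus
#' make_target(focus_grid(3, 2), 1e3)   # 9-point grid at 1 kPa
#' @export
make_target <- function(points, amplitude = 1) {
  if (is.list(points)) points <- do.call(rbind, points)
  points <- matrix(as.numeric(points), ncol = 3)
  if (nrow(points) < 1 || !all(is.finite(points)))
    ra_stop("target needs at least one finite focus point",
            "racingarray_invalid_target")
  if (nrow(points) > 1) {
    d <- as.matrix(stats::dist(points))
    if (min(d[upper.tri(d)]) == 0)
      ra_stop("duplicate focus points in target",
              "racingarray_invalid_target")
  }
  if (!is.numeric(amplitude) || length(amplitude) != 1 || amplitude < 0)
    ra_stop("amplitude must be a single non-negative number",
            "racingarray_invalid_target")
  structure(list(points = points,
                 pressure = complex(real = rep(amplitude, nrow(points)))),
            class = "target_pattern")
}

#' Square grid of focus points
#'
#' @param n_side foci per side.
#' @param spacing grid spacing, mm.
#' @param z plane depth, mm.
#' @return M x 3 matrix of focus coordinates (M = n_side^2), centred on the
#'   z axis.
#' @export
focus_grid <- function(n_side, spacing = 2, z = -12) {
  o <- (n_side - 1) / 2 * spacing
  g <- expand.grid(x = seq_len(n_side), y = seq_len(n_side))
  cbind((g$x - 1) * spacing - o, (g$y - 1) * spacing - o, z)
}

#' @export
print.target_pattern <- function(x, ...) {
  cat(sprintf("Target pattern: %d control point(s), |p| = %g Pa\n",
              nrow(x$points), Mod(x$pressure[1])))
  invisible(x)
}

# truncated-SVD right pseudoinverse solve of H U = p; optionally with a
# positive diagonal weighting W (U = W H^H (H W H^H)^{-1} p), computed via
# the SVD of H sqrt(W) for numerical symmetry
.weighted_minnorm <- function(H, p, w = NULL, truncation_tol = 1e-8) {
  M <- nrow(H); N <- ncol(H)
  if (M > N)
    ra_stop(paste("overdetermined system (more control points than",
                  "elements): use a least-squares formulation instead"),
            "racingarray_overdetermined")
  sw <- if (is.null(w)) rep(1, N) else sqrt(w)
  B <- sweep(H, 2, sw, `*`)
  sv <- svd(B)
  keep <- sv$d > truncation_tol * sv$d[1]
  if (!any(keep))
    ra_stop("all singular values truncated: rank-zero operator",
            "racingarray_rank_zero")
  # U = sqrt(W) B^+ p = sqrt(W) V diag(1/d) U^H p
  y <- Conj(t(sv$u[, keep, drop = FALSE])) %*% p
  U <- sv$v[, keep, drop = FALSE] %*% (y / sv$d[keep])
  drop(U) * sw
}

#' Minimum-norm excitation for an exact-fit pattern
#'
#' Solves `H U = p` for the excitation vector of smallest Euclidean norm,
#' `U = H^H (H H^H)^{-1} p`, via a truncated singular value decomposition
#' (singular values below `truncation_tol` times the largest are discarded;
#' control-point sets near lambda/2 spacing make the system ill-conditioned).
#'
#' @param H a `propagation_operator` or complex M x N matrix.
#' @param target a [make_target()] pattern (or complex vector `p`).
#' @param truncation_tol relative singular-value cutoff.
#' @return an `excitation_solution`: complex `coefficients` (length N),
#'   positive `weights` diagonal, relative `residual`, `iterations`, and the
#'   truncation level used.
#' @export
minimum_norm_excitation <- function(H, target, truncation_tol = 1e-8) {
  Hm <- if (inherits(H, "propagation_operator")) H$H else H
  p <- if (inherits(target, "target_pattern")) target$pressure
       else as.complex(target)
  U <- .weighted_minnorm(Hm, p, NULL, truncation_tol)
  .excitation_solution(U, rep(1, ncol(Hm)), Hm, p, 1L, TRUE, truncation_tol,
                       "minimum_norm")
}

#' Iteratively weighted minimum-norm excitation
#'
#' Refines the minimum-norm solution with a positive diagonal weighting,
#' `U = W H^H (H W H^H)^{-1} p`, to equalize drive amplitudes across
#' elements (power-limited drivers waste headroom when a few elements carry
#' most of the drive). W starts as the identity; after each solve it is
#' scaled by the reciprocal of the normalized element amplitudes,
#' `W <- W / pmax(|U| / max|U|, floor)` (floor 1e-6), renormalized to unit
#' maximum, so uniform drive amplitudes are the fixed point. This is an amplitude-equalizing interpretation of the classic
#' iterative weighting scheme; every iterate still fits the control-point
#' pressures exactly. Iteration stops when the relative change of the
#' amplitude spread `max|U| / mean|U|` falls below `amplitude_spread_tol`;
#' on non-convergence the best (smallest-spread) iterate is returned with a
#' warning flag.
#'
#' @inheritParams minimum_norm_excitation
#' @param max_iters maximum number of solves (1 reproduces the plain
#'   minimum-norm solution).
#' @param amplitude_spread_tol relative spread-change stopping tolerance.
#' @return an `excitation_solution` (see [minimum_norm_excitation()]), with
#'   `spread_trace` recording the amplitude spread per iteration.
#' @export
iterative_weighted_excitation <- function(H, target, max_iters = 20,
                                          amplitude_spread_tol = 1e-3,
                                          truncation_tol = 1e-8) {
  Hm <- if (inherits(H, "propagation_operator")) H$H else H
  p <- if (inherits(target, "target_pattern")) target$pressure
       else as.complex(target)
  stopifnot(max_iters >= 1)
  w <- rep(1, ncol(Hm))
  best <- NULL
  spread_prev <- Inf
  trace <- numeric(0)
  converged <- FALSE
  iters <- 0L
  for (it in seq_len(max_iters)) {
    U <- .weighted_minnorm(Hm, p, w, truncation_tol)
    iters <- it
    a <- Mod(U)
    spread <- if (max(a) > 0) max(a) / mean(a) else 1
    trace <- c(trace, spread)
    if (is.null(best) || spread < best$spread)
      best <- list(U = U, w = w, spread = spread, iter = it)
    if (is.finite(spread_prev) &&
        abs(spread - spread_prev) / spread_prev < amplitude_spread_tol) {
      converged <- TRUE
      break
    }
    spread_prev <- spread
    wn <- w / pmax(a / max(a), 1e-6)   # cumulative equalizing update
    w <- wn / max(wn)
  }
  if (!converged && max_iters > 1)
    ra_warn(sprintf(paste0("iterative weighting did not converge in %d ",
                           "iterations; returning best iterate (spread ",
                           "%.3f)"), max_iters, best$spread),
            "racingarray_no_convergence")
  sol <- .excitation_solution(best$U, best$w, Hm, p, iters, converged,
                              truncation_tol, "weighted")
  sol$spread_trace <- trace
  sol
}

.excitation_solution <- function(U, w, Hm, p, iterations, converged,
                                 truncation_tol, method) {
  fit <- drop(Hm %*% U)
  res <- sqrt(sum(Mod(fit - p)^2)) / max(sqrt(sum(Mod(p)^2)), .Machine$double.eps)
  structure(list(coefficients = U, weights = w, fitted = fit, prescribed = p,
                 residual = res, iterations = iterations,
                 converged = converged, truncation_tol = truncation_tol,
                 method = method),
            class = "excitation_solution")
}

#' @export
print.excitation_solution <- function(x, ...) {
  a <- Mod(x$coefficients)
  cat(sprintf(paste0("Excitation solution (%s): %d elements, %d control ",
                     "point(s)\n  relative residual %.3g, amplitude spread ",
                     "max/mean = %.3f, %d iteration(s)%s\n"),
              x$method, length(x$coefficients), length(x$prescribed),
              x$residual, if (max(a) > 0) max(a) / mean(a) else 1,
              x$iterations,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Synthesize a focus pattern with a spherical-cap array
#'
#' The central fitting routine: builds (or reuses) the element surface
#' quadrature and the forward propagation operator at the target's control
#' points, solves the inverse problem for per-element complex drives, and
#' returns a fitted-model object from which fields anywhere in the eye can
#' be predicted.
#'
#' @param geometry a `cap_array`, [array_spec()] or preset name.
#' @param target a [make_target()] pattern.
#' @param medium a [medium_spec()].
#' @param method `"weighted"` (iteratively weighted minimum norm, the
#'   default) or `"minimum_norm"`.
#' @param samples_per_wavelength surface quadrature density.
#' @param truncation_tol relative SVD truncation tolerance.
#' @param max_iters,amplitude_spread_tol weighting iteration controls.
#' @param quadrature optional pre-built [element_quadrature()] to reuse.
#' @return an object of class `focus_synthesis` with methods `print`,
#'   `summary`, `coef` (complex element drives), `fitted` (control-point
#'   pressures), `residuals`, `predict` (pressure/intensity at new points)
#'   and `plot` (focal-plane intensity map).
#' @examples
#' \donttest{
#' fit <- synthesize("type_i", make_target(c(0, 0, -12)))
#' coef(fit)[1:3]
#' predict(fit, rbind(c(0, 0, -12)))  # pressure at the focus
#' }
#' @export
synthesize <- function(geometry, target, medium = medium_spec(),
                       method = c("weighted", "minimum_norm"),
                       samples_per_wavelength = 4, truncation_tol = 1e-8,
                       max_iters = 20, amplitude_spread_tol = 1e-3,
                       quadrature = NULL) {
  method <- match.arg(method)
  if (is.character(geometry) || inherits(geometry, "array_spec"))
    geometry <- build_array(geometry)
  stopifnot(inherits(geometry, "cap_array"),
            inherits(target, "target_pattern"))
  lam <- wavelength_mm(medium, geometry$spec$f)
  if (nrow(target$points) > 1) {
    d <- as.matrix(stats::dist(target$points))
    if (min(d[upper.tri(d)]) < lam / 2)
      ra_warn(sprintf(paste0("control points closer than lambda/2 ",
                             "(%.3g mm): system may be ill-conditioned"),
                      lam / 2),
              "racingarray_close_targets")
  }
  if (is.null(quadrature))
    quadrature <- element_quadrature(geometry, medium,
                                     samples_per_wavelength)
  op <- forward_operator(quadrature, target$points, medium,
                         geometry$spec$f)
  sol <- switch(method,
    minimum_norm = minimum_norm_excitation(op, target, truncation_tol),
    weighted = iterative_weighted_excitation(op, target, max_iters,
                                             amplitude_spread_tol,
                                             truncation_tol))
  structure(list(geometry = geometry, quadrature = quadrature,
                 medium = medium, f = geometry$spec$f, target = target,
                 operator = op, solution = sol, method = method),
            class = "focus_synthesis")
}

#' @export
print.focus_synthesis <- function(x, ...) {
  cat(sprintf("Focus synthesis on array '%s' (%d elements, %g MHz)\n",
              x$geometry$spec$label, ncol(x$operator$H), x$f / 1e6))
  print(x$solution)
  invisible(x)
}

#' @export
summary.focus_synthesis <- function(object, ...) {
  print(object)
  a <- Mod(coef(object))
  cat(sprintf("  drive amplitude: min %.3g, mean %.3g, max %.3g (m/s)\n",
              min(a), mean(a), max(a)))
  if (!is.null(object$solution$spread_trace))
    cat("  spread trace:",
        paste(sprintf("%.3f", object$solution$spread_trace),
              collapse = " "), "\n")
  invisible(object)
}

#' @export
coef.focus_synthesis <- function(object, ...) object$solution$coefficients

#' @export
fitted.focus_synthesis <- function(object, ...) object$solution$fitted

#' @export
residuals.focus_synthesis <- function(object, ...)
  object$solution$fitted - object$target$pressure

#' Predict the acoustic field of a synthesized pattern
#'
#' @param object a [synthesize()] fit.
#' @param newdata observation points: an M x 3 matrix (mm), an
#'   `observation_set`, or `NULL` for the control points.
#' @param what `"pressure"` (complex, Pa), `"intensity"` (W/cm^2) or
#'   `"field"` (full `field_map`).
#' @param ... unused.
#' @export
predict.focus_synthesis <- function(object, newdata = NULL,
                                    what = c("pressure", "intensity",
                                             "field"), ...) {
  what <- match.arg(what)
  if (is.null(newdata)) newdata <- object$target$points
  fm <- pressure_field(object$quadrature, coef(object), newdata,
                       object$medium, object$f)
  switch(what, pressure = fm$pressure, intensity = fm$intensity, field = fm)
}

#' @param x a `focus_synthesis` fit.
#' @param half_extent,spacing focal-plane grid geometry, mm.
#' @rdname predict.focus_synthesis
#' @export
plot.focus_synthesis <- function(x, half_extent = 3, spacing = 0.05, ...) {
  z0 <- x$target$points[1, 3]
  g <- plane_grid("xy", center = colMeans(x$target$points)[1:2],
                  offset = z0, half_extent = half_extent, spacing = spacing)
  fm <- predict(x, g, what = "field")
  plot(fm, ...)
  invisible(fm)
}
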