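#' The "CAS" character bitmap
#'
#' A 5 x 14 monochrome raster spelling the three characters "CAS", used as
#' the stock complex stimulation pattern.
#'
#' @return 0/1 matrix, rows top-first.
#' @export
cas_bitmap <- function() {
  rows <- c(".##...##...###",
            "#....#..#.#...",
            "#....####..##.",
            "#....#..#....#",
            ".##..#..#.###.")
  do.call(rbind, lapply(strsplit(rows, ""), function(ch)
    as.integer(ch == "#")))
}

# naive Rayleigh-Sommerfeld sum written independently of the propagation
# module (plain R triple loop); the oracle side of the dual-route check
.naive_field <- function(src_mm, w_mm2, elem, U, obs_mm, medium, f) {
  k <- 2 * pi * f / medium$sound_speed
  amp <- medium$density * medium$sound_speed * k / (2 * pi)
  p <- complex(length.out = nrow(obs_mm))
  for (m in seq_len(nrow(obs_mm))) {
    acc <- 0 + 0i
    for (s in seq_len(nrow(src_mm))) {
      r <- sqrt(sum((obs_mm[m, ] - src_mm[s, ])^2)) * 1e-3
      acc <- acc + U[elem[s]] * exp(-1i * k * r) / r * (w_mm2[s] * 1e-6)
    }
    p[m] <- 1i * amp * acc
  }
  p
}

#' Deterministic test fixtures
#'
#' Writes small, plain-text fixture files for a given kind and seed:
#' \describe{
#'   \item{`focus_grid`}{a JSON list of 3 x 3 grid foci at z = -12.}
#'   \item{`cas_bitmap`}{the "CAS" raster as a text bitmap.}
#'   \item{`random_small_array`}{a random <= 16-element cap geometry
#'     (CSV), a random excitation (CSV) and the brute-force pressure table
#'     (CSV) at random observation points, computed here by an independent
#'     naive summation so propagation-module output can be checked against
#'     it.}
#' }
#' Outputs are deterministic for a given seed.
#'
#' @param kind fixture kind.
#' @param seed integer seed.
#' @param dir output directory (created if needed).
#' @return named character vector of written paths.
#' @export
fixture_generator <- function(kind = c("focus_grid", "cas_bitmap",
                                       "random_small_array"),
                              seed = 1, dir = tempdir()) {
  kind <- tryCatch(match.arg(kind),
                   error = function(e)
                     ra_stop(sprintf("unknown fixture kind '%s'", kind[1]),
                             "racingarray_invalid_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(as.integer(seed))
  if (kind == "focus_grid") {
    path <- file.path(dir, "focus_grid.json")
    jsonlite::write_json(list(foci = focus_grid(3, 2, -12), amplitude = 1),
                         path, digits = NA)
    return(c(foci = path))
  }
  if (kind == "cas_bitmap") {
    path <- file.path(dir, "cas_bitmap.txt")
    write_bitmap(cas_bitmap(), path)
    return(c(bitmap = path))
  }
  # random_small_array: tiny annular cap with a randomized band; values are
  # rounded so the plain-text fixtures round-trip exactly
  n <- sample(3:16, 1)
  din <- round(runif(1, 0, 6), 6)
  dout <- round(din + runif(1, 4, 8), 6)
  w <- 1.5
  spec <- geom <- NULL
  repeat {
    spec <- array_spec(f = 1e6, n_elements = n, inner_diameter_mm = din,
                       outer_diameter_mm = dout, element_width_mm = w,
                       element_height_mm = 1.5, roc_mm = 12,
                       label = sprintf("random_seed%d", as.integer(seed)))
    geom <- tryCatch(build_array(spec), racingarray_infeasible_tiling =
                       function(e) NULL)
    if (!is.null(geom) || w < 0.1) break
    w <- w / 2  # narrow the elements until the band holds them
  }
  medium <- medium_spec()
  quad <- element_quadrature(geom, medium, 2)
  U <- complex(real = round(rnorm(n), 6), imaginary = round(rnorm(n), 6))
  obs <- round(cbind(runif(12, -4, 4), runif(12, -4, 4),
                     runif(12, -14, -8)), 3)
  p <- .naive_field(quad$points, quad$weights, quad$element, U, obs,
                    medium, spec$f)
  gpath <- file.path(dir, "random_small_array_geometry.csv")
  upath <- file.path(dir, "random_small_array_excitation.csv")
  fpath <- file.path(dir, "random_small_array_field.csv")
  write_geometry_csv(geom, gpath)
  utils::write.csv(data.frame(index = seq_len(n), re = Re(U), im = Im(U)),
                   upath, row.names = FALSE)
  utils::write.csv(data.frame(x = obs[, 1], y = obs[, 2], z = obs[, 3],
                              re_p = Re(p), im_p = Im(p)),
                   fpath, row.names = FALSE)
  c(geometry = gpath, excitation = upath, field = fpath,
    spec = {
      spath <- file.path(dir, "random_small_array_spec.json")
      jsonlite::write_json(unclass(spec), spath, auto_unbox = TRUE,
                           digits = NA)
      spath
    })
}
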