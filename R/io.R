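#' Load a scenario configuration
#'
#' Reads a YAML or JSON scenario (array preset or explicit spec, medium,
#' solver settings, grid settings, target descriptor, seed), validates it
#' strictly (unknown keys are rejected, naming the offender) and applies the
#' documented defaults. Provenance (source path, package version) is
#' attached to the result.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return object of class `scenario_config`.
#' @export
load_scenario <- function(path) {
  if (!file.exists(path))
    ra_stop(sprintf("scenario file not found: %s", path),
            "racingarray_invalid_config")
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  cfg <- validate_scenario(raw)
  attr(cfg, "provenance") <- list(path = normalizePath(path),
                                  package_version =
                                    as.character(utils::packageVersion("racingarray")))
  cfg
}

.check_keys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    ra_stop(sprintf("unknown key '%s' in %s", bad[1], where),
            "racingarray_invalid_config")
}

#' Validate a scenario list
#'
#' @param raw a named list as read from YAML/JSON.
#' @return a `scenario_config` with defaults applied.
#' @export
validate_scenario <- function(raw) {
  if (!is.list(raw))
    ra_stop("scenario must be a mapping", "racingarray_invalid_config")
  .check_keys(raw, c("array", "medium", "solver", "grid", "target", "seed"),
              "scenario")
  # array: preset string or explicit spec
  arr <- raw$array
  if (is.null(arr))
    ra_stop("scenario must name an array (preset or explicit spec)",
            "racingarray_invalid_config")
  spec <- if (is.character(arr)) preset_array(arr)
  else {
    .check_keys(arr, c("preset", "f", "n_elements", "inner_diameter_mm",
                       "outer_diameter_mm", "element_width_mm",
                       "element_height_mm", "roc_mm", "label"), "array")
    if (!is.null(arr$preset)) preset_array(arr$preset)
    else array_spec(f = arr$f, n_elements = arr$n_elements,
                    inner_diameter_mm = arr$inner_diameter_mm,
                    outer_diameter_mm = arr$outer_diameter_mm,
                    element_width_mm = arr$element_width_mm,
                    element_height_mm = arr$element_height_mm,
                    roc_mm = if (is.null(arr$roc_mm)) 12 else arr$roc_mm,
                    label = if (is.null(arr$label)) "custom" else arr$label)
  }
  med <- raw$medium
  if (!is.null(med))
    .check_keys(med, c("sound_speed", "density"), "medium")
  medium <- medium_spec(
    sound_speed = if (is.null(med$sound_speed)) 1500 else med$sound_speed,
    density = if (is.null(med$density)) 1000 else med$density)
  sol <- raw$solver
  if (!is.null(sol))
    .check_keys(sol, c("method", "truncation_tol", "max_iters",
                       "amplitude_spread_tol", "samples_per_wavelength"),
                "solver")
  solver <- list(
    method = if (is.null(sol$method)) "weighted" else sol$method,
    truncation_tol = if (is.null(sol$truncation_tol)) 1e-8
                     else sol$truncation_tol,
    max_iters = if (is.null(sol$max_iters)) 20 else sol$max_iters,
    amplitude_spread_tol = if (is.null(sol$amplitude_spread_tol)) 1e-3
                           else sol$amplitude_spread_tol,
    samples_per_wavelength = if (is.null(sol$samples_per_wavelength)) 4
                             else sol$samples_per_wavelength)
  grd <- raw$grid
  if (!is.null(grd))
    .check_keys(grd, c("plane_half_extent", "plane_spacing",
                       "profile_spacing"), "grid")
  grid <- list(
    plane_half_extent = if (is.null(grd$plane_half_extent)) 3
                        else grd$plane_half_extent,
    plane_spacing = if (is.null(grd$plane_spacing)) 0.05
                    else grd$plane_spacing,
    profile_spacing = if (is.null(grd$profile_spacing)) 0.02
                      else grd$profile_spacing)
  tgt <- raw$target
  if (!is.null(tgt)) {
    .check_keys(tgt, c("foci", "grid_n", "grid_spacing", "z", "bitmap",
                       "bitmap_pitch", "amplitude"), "target")
    if (is.null(tgt$foci) && is.null(tgt$grid_n) && is.null(tgt$bitmap))
      ra_stop("target must give foci, grid_n or bitmap",
              "racingarray_invalid_config")
  }
  structure(list(array = spec, medium = medium, solver = solver,
                 grid = grid, target = tgt,
                 seed = if (is.null(raw$seed)) NULL
                        else as.integer(raw$seed)),
            class = "scenario_config")
}

#' Materialize a scenario's target pattern
#'
#' @param cfg a `scenario_config`.
#' @return a `target_pattern` (single posterior-retina focus when the
#'   scenario gives no target).
#' @export
scenario_target <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  tgt <- cfg$target
  if (is.null(tgt)) return(make_target(c(0, 0, -12)))
  amp <- if (is.null(tgt$amplitude)) 1 else tgt$amplitude
  z <- if (is.null(tgt$z)) -12 else tgt$z
  if (!is.null(tgt$foci)) {
    pts <- if (is.list(tgt$foci)) do.call(rbind, tgt$foci)
           else matrix(unlist(tgt$foci), ncol = 3, byrow = TRUE)
    return(make_target(pts, amp))
  }
  if (!is.null(tgt$grid_n)) {
    sp <- if (is.null(tgt$grid_spacing)) 2 else tgt$grid_spacing
    return(make_target(focus_grid(tgt$grid_n, sp, z), amp))
  }
  bm_path <- tgt$bitmap
  if (!file.exists(bm_path)) {
    # try relative to the scenario file itself
    prov <- attr(cfg, "provenance")
    if (!is.null(prov$path)) {
      alt <- file.path(dirname(prov$path), bm_path)
      if (file.exists(alt)) bm_path <- alt
    }
  }
  bm <- read_bitmap(bm_path)
  pitch <- if (is.null(tgt$bitmap_pitch)) 1 else tgt$bitmap_pitch
  bitmap_target(bm, pitch, z, amp)
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("Scenario configuration\n")
  print(x$array)
  print(x$medium)
  cat(sprintf("  solver: %s (truncation %g, max %d iters)\n",
              x$solver$method, x$solver$truncation_tol, x$solver$max_iters))
  invisible(x)
}

#' Read/write a plain-text monochrome bitmap
#'
#' The format is trivially diffable: one row per line, `#`/`1` for on,
#' `.`/`0`/space for off.
#'
#' @param path file path.
#' @return 0/1 matrix.
#' @export
read_bitmap <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(strsplit(lines, ""), function(ch)
    as.integer(ch %in% c("#", "1")))
  n <- max(lengths(rows))
  do.call(rbind, lapply(rows, function(r) c(r, integer(n - length(r)))))
}

#' @param bitmap 0/1 matrix.
#' @rdname read_bitmap
#' @export
write_bitmap <- function(bitmap, path) {
  writeLines(apply(bitmap, 1, function(r)
    paste(ifelse(r != 0, "#", "."), collapse = "")), path)
  invisible(path)
}

#' Export an excitation solution as CSV
#'
#' Columns: element index, amplitude, phase in degrees.
#'
#' @param fit a [synthesize()] fit or `excitation_solution`.
#' @param path output path.
#' @export
write_excitation_csv <- function(fit, path) {
  U <- if (inherits(fit, "focus_synthesis")) coef(fit)
       else fit$coefficients
  utils::write.csv(data.frame(index = seq_along(U), amplitude = Mod(U),
                              phase_deg = Arg(U) * 180 / pi),
                   path, row.names = FALSE)
  invisible(path)
}

#' Export a field map as CSV (long format)
#'
#' @param field a `field_map`.
#' @param path output path.
#' @export
write_field_csv <- function(field, path) {
  stopifnot(inherits(field, "field_map"))
  utils::write.csv(data.frame(x = field$obs$points[, 1],
                              y = field$obs$points[, 2],
                              z = field$obs$points[, 3],
                              re_p = Re(field$pressure),
                              im_p = Im(field$pressure),
                              intensity_W_cm2 = field$intensity),
                   path, row.names = FALSE)
  invisible(path)
}

#' Render a plane field map to PNG
#'
#' @param field a `field_map` on a [plane_grid()].
#' @param path output PNG path.
#' @param width,height device size in pixels.
#' @export
save_field_png <- function(field, path, width = 600, height = 600) {
  grDevices::png(path, width = width, height = height)
  on.exit(grDevices::dev.off())
  plot(field)
  invisible(path)
}

#' Write a reproducibility manifest
#'
#' Records the scenario (inline), its md5 hash, the package version and the
#' seed, enough to reproduce a deterministic run bit-for-bit.
#'
#' @param path output JSON path.
#' @param cfg a `scenario_config` (or any serializable list).
#' @param seed integer seed used for randomized fixtures (`NA` if none).
#' @export
write_manifest <- function(path, cfg, seed = NA_integer_) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  payload <- jsonlite::serializeJSON(unclass(cfg))
  writeLines(payload, tmp)
  jsonlite::write_json(
    list(config = unclass(cfg),
         config_md5 = unname(tools::md5sum(tmp)),
         package_version = as.character(utils::packageVersion("racingarray")),
         r_version = R.version.string,
         seed = seed),
    path, auto_unbox = TRUE, digits = NA, null = "null", force = TRUE)
  invisible(path)
}
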