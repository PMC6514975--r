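test_that("preset tilings realize the published element counts and sizes", {
  for (label in c("type_a", "type_e", "type_i", "type_m")) {
    spec <- preset_array(label)
    geom <- build_array(spec)
    el <- geom$elements
    expect_identical(nrow(el), as.integer(spec$n_elements))
    # realized arc dimensions within 25% of the nominal element size
    rs <- realized_element_size(geom)
    expect_lt(abs(rs["width"] - spec$element_width_mm) /
                spec$element_width_mm, 0.25)
    expect_lt(abs(rs["height"] - spec$element_height_mm) /
                spec$element_height_mm, 0.25)
    # centres on the sphere, normals inward, exact spherical areas
    R <- spec$roc_mm
    r <- sqrt(el$cx^2 + el$cy^2 + el$cz^2)
    expect_lt(max(abs(r - R)) / R, 1e-9)
    expect_lt(max(abs(el$nx + el$cx / R)), 1e-12)
    area <- R^2 * (cos(el$phi1) - cos(el$phi2)) * (el$theta2 - el$theta1)
    expect_lt(max(abs(area - el$area_mm2) / area), 1e-9)
    # all elements inside the annular band (tolerance one element height)
    band <- geom$band_angles
    expect_gte(min(el$phi1), band[1] - spec$element_height_mm / R)
    expect_lte(max(el$phi2), band[2] + spec$element_height_mm / R)
    # total active area cannot exceed the band area
    expect_lte(sum(el$area_mm2), band_area_mm2(spec))
  }
})

test_that("elements never overlap in angle", {
  geom <- build_array("type_i")
  el <- geom$elements
  for (k in unique(el$ring)) {
    d <- el[el$ring == k, ]
    d <- d[order(d$theta1), ]
    expect_true(all(diff(d$phi1) == 0))          # one polar band per ring
    expect_true(all(d$theta1[-1] >= d$theta2[-nrow(d)] - 1e-12))
    # wrap-around gap
    expect_gte(d$theta1[1] + 2 * pi, d$theta2[nrow(d)] - 1e-12)
  }
  # rings are disjoint polar bands
  bands <- unique(el[, c("ring", "phi1", "phi2")])
  bands <- bands[order(bands$phi1), ]
  expect_true(all(bands$phi1[-1] >= bands$phi2[-nrow(bands)] - 1e-12))
})

test_that("azimuthally uniform rings map onto themselves under ring-pitch rotation", {
  geom <- build_array("type_e")
  el <- geom$elements
  for (k in unique(el$ring)) {
    d <- el[el$ring == k, ]
    pitch <- 2 * pi / nrow(d)
    rot <- cbind(d$cx * cos(pitch) - d$cy * sin(pitch),
                 d$cx * sin(pitch) + d$cy * cos(pitch), d$cz)
    # every rotated centre coincides with some original centre
    for (i in seq_len(nrow(d))) {
      dist <- sqrt((d$cx - rot[i, 1])^2 + (d$cy - rot[i, 2])^2 +
                     (d$cz - rot[i, 3])^2)
      expect_lt(min(dist), 1e-9)
    }
  }
})

test_that("a single element can cover a whole cap, and over-full requests fail", {
  R <- 12; phi2 <- asin(7 / 12)
  spec <- array_spec(f = 1e6, n_elements = 1, inner_diameter_mm = 0,
                     outer_diameter_mm = 14,
                     element_width_mm = 2 * pi * R * sin(phi2 / 2),
                     element_height_mm = R * phi2)
  geom <- build_array(spec)
  expect_identical(nrow(geom$elements), 1L)
  expect_equal(geom$elements$area_mm2, 2 * pi * R^2 * (1 - cos(phi2)),
               tolerance = 1e-9)
  # asking for far more elements than the band holds at nominal size
  expect_error(build_array(array_spec(f = 5e6, n_elements = 50000,
                                      inner_diameter_mm = 10,
                                      outer_diameter_mm = 18,
                                      element_width_mm = 0.37,
                                      element_height_mm = 0.50)),
               class = "racingarray_infeasible_tiling")
  err <- tryCatch(build_array(array_spec(f = 5e6, n_elements = 50000,
                                         inner_diameter_mm = 10,
                                         outer_diameter_mm = 18,
                                         element_width_mm = 0.37,
                                         element_height_mm = 0.50)),
                  error = function(e) conditionMessage(e))
  expect_match(err, "ring")
})

test_that("quadrature weights tile each element exactly and refine correctly", {
  m <- medium_spec()
  geom <- small_test_geometry()
  quad <- element_quadrature(geom, m, 4)
  sums <- tapply(quad$weights, quad$element, sum)
  sums <- as.numeric(sums[order(as.integer(names(sums)))])
  expect_equal(sums, geom$elements$area_mm2, tolerance = 1e-12)
  # all source points on the sphere
  r <- sqrt(rowSums(quad$points^2))
  expect_lt(max(abs(r - 12)) / 12, 1e-12)
  # hemisphere closed form: full-cap single element, theta complete
  R <- 12
  hemi <- build_array(array_spec(f = 1e6, n_elements = 1,
                                 inner_diameter_mm = 0,
                                 outer_diameter_mm = 2 * R,
                                 element_width_mm = 2 * pi * R * sin(pi / 4),
                                 element_height_mm = R * pi / 2))
  qh <- element_quadrature(hemi, m, 4)
  expect_equal(sum(qh$weights), 2 * pi * R^2, tolerance = 1e-12)
  expect_error(element_quadrature(geom, m, 1),
               class = "racingarray_invalid_quadrature")
})

test_that("focal pressure converges as the quadrature is refined", {
  m <- medium_spec()
  geom <- small_test_geometry(n = 8, f = 1e6)
  obs <- rbind(c(0.3, -0.2, -11))
  # focused (phase-conjugate) drive so the focal pressure is the coherent sum
  U <- Conj(drop(forward_operator(element_quadrature(geom, m, 4), obs, m)$H))
  p_at <- function(spw) {
    q <- element_quadrature(geom, m, spw)
    pressure_field(q, U, obs, m)$pressure
  }
  ref <- p_at(24)  # 4x finer than the finest tested level
  errs <- sapply(c(2, 3, 4, 6), function(s) Mod(p_at(s) - ref) / Mod(ref))
  expect_lt(errs[4], errs[1])
  expect_true(all(diff(errs) < 1e-3))  # essentially non-increasing
  # doubling the sampling rate moves the focal pressure by < 0.5%
  expect_lt(Mod(p_at(8) - p_at(4)) / Mod(p_at(4)), 0.005)
})

test_that("aperture report reproduces the closed-form band geometry", {
  geom <- build_array("type_i")
  rep_ <- aperture_report(geom)
  band <- 2 * pi * 144 * (sqrt(119) - sqrt(63)) / 12
  expect_equal(rep_$band_area_mm2, band, tolerance = 1e-12)
  expect_equal(rep_$active_area_mm2, 512 * 0.37 * 0.50, tolerance = 0.01)
  expect_equal(rep_$fill_factor, 512 * 0.37 * 0.50 / band, tolerance = 0.01)
  # realized pitch exceeds the 0.3 mm wavelength: grating lobes possible
  expect_gt(rep_$max_pitch_ratio, 1)
  # a single full-cap element fills its band completely
  R <- 12; phi2 <- asin(7 / 12)
  one <- build_array(array_spec(f = 1e6, n_elements = 1,
                                inner_diameter_mm = 0, outer_diameter_mm = 14,
                                element_width_mm = 2 * pi * R * sin(phi2 / 2),
                                element_height_mm = R * phi2))
  expect_equal(aperture_report(one)$fill_factor, 1, tolerance = 1e-9)
})

test_that("wavelength-pitch element counts scale and bound as expected", {
  spec <- preset_array("type_q")  # 10 MHz racing band
  n10 <- required_element_count(spec)
  expect_gt(n10, 3000)
  expect_true(n10 > 9000 && n10 < 11000)
  for (c0 in c(1480, 1540))
    expect_gt(required_element_count(spec, medium_spec(sound_speed = c0)),
              3000)
  n5 <- required_element_count(preset_array("type_i"))
  expect_equal(n10 / n5, 4, tolerance = 1e-3)  # lambda halves, count x4
  degenerate <- list(f = 1e7, inner_diameter_mm = 10, outer_diameter_mm = 10,
                     roc_mm = 12)
  expect_identical(required_element_count(degenerate), 0L)
})

test_that("geometry exports round-trip through CSV", {
  geom <- small_test_geometry()
  path <- withr::local_tempfile(fileext = ".csv")
  write_geometry_csv(geom, path)
  back <- read.csv(path)
  expect_equal(back$cx, geom$elements$cx, tolerance = 1e-12)
  expect_equal(back$area_mm2, geom$elements$area_mm2, tolerance = 1e-12)
})
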