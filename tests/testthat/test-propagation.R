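test_that("operator matches the independent brute-force summation", {
  set.seed(11)
  m <- medium_spec()
  geom <- build_array(array_spec(f = 1e6, n_elements = 3,
                                 inner_diameter_mm = 6,
                                 outer_diameter_mm = 12,
                                 element_width_mm = 3,
                                 element_height_mm = 3))
  quad <- element_quadrature(geom, m, 3)
  obs <- cbind(runif(8, -4, 4), runif(8, -4, 4), runif(8, -14, -8))
  H <- forward_operator(quad, obs, m)$H
  H0 <- naive_rs_operator(quad, obs, m, geom$spec$f)
  expect_lt(max(Mod(H - H0)) / max(Mod(H0)), 1e-12)
  # streamed field equals the explicit H %*% U product
  U <- rcomplex(3)
  fm <- pressure_field(quad, U, obs, m, block = 3L)
  expect_lt(max(Mod(fm$pressure - drop(H %*% U))) / max(Mod(fm$pressure)),
            1e-12)
  p0 <- naive_rs_pressure(quad, U, obs, m, geom$spec$f)
  expect_lt(max(Mod(fm$pressure - p0)) / max(Mod(p0)), 1e-12)
})

test_that("a tiny element reduces to the point-source kernel", {
  m <- medium_spec()
  # 0.01 mm element at 100 kHz (lambda = 15 mm): one quadrature node
  geom <- build_array(array_spec(f = 1e5, n_elements = 1,
                                 inner_diameter_mm = 0,
                                 outer_diameter_mm = 0.03,
                                 element_width_mm = 0.01,
                                 element_height_mm = 0.01))
  quad <- element_quadrature(geom, m, 4)
  expect_identical(nrow(quad$points), 1L)
  r_mm <- 7
  obs <- rbind(c(0, 0, 12 - r_mm))  # along the apex normal
  H <- forward_operator(quad, obs, m)$H
  k <- 2 * pi * geom$spec$f / m$sound_speed
  dS <- quad$weights * 1e-6
  r <- sqrt(sum((obs - quad$points)^2)) * 1e-3
  expect_equal(Mod(H[1, 1]),
               m$density * m$sound_speed * k * dS / (2 * pi * r),
               tolerance = 1e-12)
})

test_that("on-axis symmetry: a complete ring gives equal |H| entries", {
  m <- medium_spec()
  geom <- build_array(array_spec(f = 1e6, n_elements = 16,
                                 inner_diameter_mm = 10,
                                 outer_diameter_mm = 11.5,
                                 element_width_mm = 1.5,
                                 element_height_mm = 1))
  expect_identical(geom$n_rings, 1L)
  quad <- element_quadrature(geom, m, 4)
  H <- forward_operator(quad, rbind(c(0, 0, -12)), m)$H
  expect_lt(diff(range(Mod(H))) / max(Mod(H)), 1e-9)
})

test_that("the field is linear in the excitation and vanishes for zero drive", {
  set.seed(7)
  m <- medium_spec()
  geom <- small_test_geometry()
  quad <- element_quadrature(geom, m, 3)
  obs <- cbind(runif(6, -3, 3), runif(6, -3, 3), runif(6, -13, -9))
  n <- geom$spec$n_elements
  U1 <- rcomplex(n); U2 <- rcomplex(n)
  a <- 1.7 - 0.3i; b <- -0.4 + 2.1i
  p1 <- pressure_field(quad, U1, obs, m)$pressure
  p2 <- pressure_field(quad, U2, obs, m)$pressure
  p12 <- pressure_field(quad, a * U1 + b * U2, obs, m)$pressure
  expect_lt(max(Mod(p12 - (a * p1 + b * p2))) / max(Mod(p12)), 1e-10)
  p0 <- pressure_field(quad, rep(0 + 0i, n), obs, m)
  expect_true(all(p0$pressure == 0) && all(p0$intensity == 0))
})

test_that("a small element's on-axis pressure decays as 1/r", {
  m <- medium_spec()
  geom <- build_array(array_spec(f = 1e6, n_elements = 1,
                                 inner_diameter_mm = 0,
                                 outer_diameter_mm = 0.6,
                                 element_width_mm = 0.2,
                                 element_height_mm = 0.2))
  quad <- element_quadrature(geom, m, 4)
  r_mm <- c(4, 8, 16, 24)  # >= 20x the 0.2 mm element extent
  obs <- cbind(0, 0, 12 - r_mm)
  p <- pressure_field(quad, 1 + 0i, obs, m)$pressure
  pr <- Mod(p) * r_mm
  expect_lt(diff(range(pr)) / max(pr), 0.01)
})

test_that("the centre-of-curvature closed form holds for every geometry", {
  m <- medium_spec()
  for (geom in list(build_array("type_e"), small_test_geometry())) {
    quad <- element_quadrature(geom, m, 4)
    n <- geom$spec$n_elements
    p <- pressure_field(quad, rep(1 + 0i, n), rbind(c(0, 0, 0)), m)$pressure
    expect_equal(Mod(p), analytic_focus_pressure(geom, m),
                 tolerance = 5e-3)
  }
  # full hemisphere: |p| = rho c k R
  R <- 12
  hemi <- build_array(array_spec(f = 1e6, n_elements = 1,
                                 inner_diameter_mm = 0,
                                 outer_diameter_mm = 2 * R,
                                 element_width_mm = 2 * pi * R * sin(pi / 4),
                                 element_height_mm = R * pi / 2))
  k <- 2 * pi * 1e6 / m$sound_speed
  expect_equal(analytic_focus_pressure(hemi, m),
               m$density * m$sound_speed * k * (R * 1e-3),
               tolerance = 1e-12)
})

test_that("intensity follows |p|^2 / (2 rho c) with quadratic scaling", {
  m <- medium_spec()
  expect_equal(intensity_W_cm2(1 + 0i, m), 1 / (2 * 1000 * 1500) * 1e-4,
               tolerance = 1e-12)
  expect_identical(intensity_W_cm2(0i, m), 0)
  geom <- small_test_geometry()
  quad <- element_quadrature(geom, m, 3)
  obs <- rbind(c(0, 0, -12), c(1, 1, -10))
  U <- rcomplex(geom$spec$n_elements)
  I1 <- pressure_field(quad, U, obs, m)$intensity
  I2 <- pressure_field(quad, 2 * U, obs, m)$intensity
  expect_equal(I2, 4 * I1, tolerance = 1e-12)
  expect_true(all(I1 >= 0))
})

test_that("observation points on the source surface are rejected", {
  m <- medium_spec()
  geom <- small_test_geometry()
  quad <- element_quadrature(geom, m, 3)
  on_surface <- quad$points[1, , drop = FALSE]
  expect_error(forward_operator(quad, on_surface, m),
               class = "racingarray_near_singular_kernel")
  expect_error(pressure_field(quad, rep(1 + 0i, 12), on_surface, m),
               class = "racingarray_near_singular_kernel")
})
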