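# Independent brute-force Rayleigh-Sommerfeld oracle: plain triple loop over
# observation points and quadrature sources, written without reference to the
# package's kernel. Distances in mm, converted to SI here.
naive_rs_pressure <- function(quad, U, obs_mm, medium, f) {
  k <- 2 * pi * f / medium$sound_speed
  amp <- medium$density * medium$sound_speed * k / (2 * pi)
  obs_mm <- matrix(obs_mm, ncol = 3)
  p <- complex(length.out = nrow(obs_mm))
  for (m in seq_len(nrow(obs_mm))) {
    acc <- 0 + 0i
    for (s in seq_len(nrow(quad$points))) {
      r_m <- sqrt(sum((obs_mm[m, ] - quad$points[s, ])^2)) * 1e-3
      acc <- acc + U[quad$element[s]] *
        exp(-1i * k * r_m) / r_m * (quad$weights[s] * 1e-6)
    }
    p[m] <- 1i * amp * acc
  }
  p
}

naive_rs_operator <- function(quad, obs_mm, medium, f) {
  N <- quad$n_elements
  H <- matrix(0 + 0i, nrow(matrix(obs_mm, ncol = 3)), N)
  for (n in seq_len(N)) {
    U <- complex(length.out = N)
    U[n] <- 1 + 0i
    H[, n] <- naive_rs_pressure(quad, U, obs_mm, medium, f)
  }
  H
}

# small annular test array: 12 elements on one-ish rings, cheap quadrature
small_test_geometry <- function(n = 12, f = 1e6) {
  build_array(array_spec(f = f, n_elements = n, inner_diameter_mm = 8,
                         outer_diameter_mm = 14, element_width_mm = 2,
                         element_height_mm = 2, roc_mm = 12,
                         label = "test_small"))
}

# seeded random complex matrix / vector helpers for solver tests
rcomplex <- function(n) complex(real = rnorm(n), imaginary = rnorm(n))
rcmat <- function(m, n) matrix(rcomplex(m * n), m, n)
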