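#include <Rcpp.h>
#include <complex>
using namespace Rcpp;

// Rayleigh-Sommerfeld kernel sums. Coordinates in metres, k in rad/m,
// weights in m^2. `amp` carries rho*c*k/(2*pi); the leading factor j is
// applied here so callers receive p = (j rho c k / 2 pi) sum u e^{-jkr}/r dS.

// Forward operator H (M x N): column n accumulates the kernel over the
// quadrature points belonging to element n (elem is 0-based).
// [[Rcpp::export]]
ComplexMatrix rs_operator_cpp(NumericMatrix obs, NumericMatrix src,
                              NumericVector w, IntegerVector elem,
                              int n_elem, double k, double amp) {
  const int M = obs.nrow(), S = src.nrow();
  std::vector< std::complex<double> > H((size_t)M * n_elem,
                                        std::complex<double>(0.0, 0.0));
  const std::complex<double> j_amp(0.0, amp);
  for (int m = 0; m < M; ++m) {
    const double ox = obs(m, 0), oy = obs(m, 1), oz = obs(m, 2);
    for (int s = 0; s < S; ++s) {
      const double dx = ox - src(s, 0), dy = oy - src(s, 1),
                   dz = oz - src(s, 2);
      const double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      const double ph = -k * r;
      const double g = w[s] / r;
      H[(size_t)elem[s] * M + m] +=
        std::complex<double>(g * std::cos(ph), g * std::sin(ph));
    }
  }
  ComplexMatrix out(M, n_elem);
  for (size_t i = 0; i < H.size(); ++i) {
    const std::complex<double> v = j_amp * H[i];
    out[i].r = v.real();
    out[i].i = v.imag();
  }
  return out;
}

// Pressure field p (length M) for a fixed excitation: `wu` holds the
// per-source complex product w_s * U_{elem(s)} so the whole array collapses
// to a single weighted sum and H is never materialised.
// [[Rcpp::export]]
ComplexVector rs_field_cpp(NumericMatrix obs, NumericMatrix src,
                           ComplexVector wu, double k, double amp) {
  const int M = obs.nrow(), S = src.nrow();
  ComplexVector out(M);
  const std::complex<double> j_amp(0.0, amp);
  for (int m = 0; m < M; ++m) {
    const double ox = obs(m, 0), oy = obs(m, 1), oz = obs(m, 2);
    std::complex<double> acc(0.0, 0.0);
    for (int s = 0; s < S; ++s) {
      const double dx = ox - src(s, 0), dy = oy - src(s, 1),
                   dz = oz - src(s, 2);
      const double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      const double ph = -k * r;
      const std::complex<double> u(wu[s].r, wu[s].i);
      acc += u * std::complex<double>(std::cos(ph) / r, std::sin(ph) / r);
    }
    const std::complex<double> v = j_amp * acc;
    out[m].r = v.real();
    out[m].i = v.imag();
  }
  return out;
}

// Minimum distance between any observation point and any source point,
// used for the near-singular-kernel guard.
// [[Rcpp::export]]
double rs_min_dist_cpp(NumericMatrix obs, NumericMatrix src) {
  const int M = obs.nrow(), S = src.nrow();
  double best = R_PosInf;
  for (int m = 0; m < M; ++m) {
    const double ox = obs(m, 0), oy = obs(m, 1), oz = obs(m, 2);
    for (int s = 0; s < S; ++s) {
      const double dx = ox - src(s, 0), dy = oy - src(s, 1),
                   dz = oz - src(s, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
  }
  return std::sqrt(best);
}
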