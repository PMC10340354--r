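#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Sample-time convention (shared by both kernels): R-side sample n (1-based)
// has receive time t0 + (n - 1) / fs relative to the transmit instant.
// Internally samples are 0-based: time(n0) = t0 + n0 / fs.

// Synthesize RF channel data for point scatterers.
//
// txrows: one row per (event, firing element): event (0-based), x, z,
//         dir_x, dir_z (unit normal), t_offset (s), weight.
// rx:     K x 4: x, z, dir_x, dir_z.
// scat:   S x 3: x, z, amplitude.
// Pulse: Gaussian-windowed cosine at f0, envelope sd sigma_t (s), truncated
// at +/- 4 sigma_t. Directivity per element: cos(theta) clipped at 0 times
// the hard-baffle element-width factor sinc(w sin(theta) / lambda)
// (w_over_lambda = 0 disables the width factor); spreading
// 1 / max(d_tx * d_rx, eps).
// [[Rcpp::export]]
NumericVector simrf_kernel(int T, int K, int N,
                           NumericMatrix txrows, NumericMatrix rx,
                           NumericMatrix scat,
                           double fs, double t0, double f0,
                           double sigma_t, double c_mm, double eps,
                           double w_over_lambda) {
  NumericVector rf((R_xlen_t)T * K * N);
  const double twopif0 = 2.0 * M_PI * f0;
  const double half_support = 4.0 * sigma_t;
  const int S = scat.nrow();
  const int ntx = txrows.nrow();
  std::vector<double> drx(K), dir_rx(K);
  auto sinc = [](double x) {
    return (std::fabs(x) < 1e-12) ? 1.0 : std::sin(M_PI * x) / (M_PI * x);
  };

  for (int s = 0; s < S; ++s) {
    const double xs = scat(s, 0), zs = scat(s, 1), as = scat(s, 2);
    if (as == 0.0) continue;
    for (int r = 0; r < K; ++r) {
      const double dx = xs - rx(r, 0), dz = zs - rx(r, 1);
      const double d = std::sqrt(dx * dx + dz * dz);
      drx[r] = d;
      double ct = 1.0, st = 0.0;
      if (d > 0) {
        ct = (dx * rx(r, 2) + dz * rx(r, 3)) / d;
        st = (dx * rx(r, 3) - dz * rx(r, 2)) / d;
      }
      dir_rx[r] = (ct > 0.0) ? ct * sinc(w_over_lambda * st) : 0.0;
    }
    for (int j = 0; j < ntx; ++j) {
      const int ev = (int)txrows(j, 0);
      const double dx = xs - txrows(j, 1), dz = zs - txrows(j, 2);
      const double dtx = std::sqrt(dx * dx + dz * dz);
      double ctx = 1.0, stx = 0.0;
      if (dtx > 0) {
        ctx = (dx * txrows(j, 3) + dz * txrows(j, 4)) / dtx;
        stx = (dx * txrows(j, 4) - dz * txrows(j, 3)) / dtx;
      }
      if (ctx <= 0.0) continue;
      ctx *= sinc(w_over_lambda * stx);
      const double toff = txrows(j, 5), w = txrows(j, 6);
      for (int r = 0; r < K; ++r) {
        if (dir_rx[r] == 0.0) continue;
        const double tau = toff + (dtx + drx[r]) / c_mm;
        const double amp = as * w * ctx * dir_rx[r] /
          std::max(dtx * drx[r], eps);
        const int n_lo = std::max(
          0, (int)std::ceil((tau - half_support - t0) * fs));
        const int n_hi = std::min(
          N - 1, (int)std::floor((tau + half_support - t0) * fs));
        if (n_lo > n_hi) continue;
        const R_xlen_t base = (R_xlen_t)ev + (R_xlen_t)T * r;
        for (int n = n_lo; n <= n_hi; ++n) {
          const double u = t0 + n / fs - tau;
          rf[base + (R_xlen_t)T * K * n] +=
            amp * std::exp(-u * u / (2.0 * sigma_t * sigma_t)) *
            std::cos(twopif0 * u);
        }
      }
    }
  }
  return rf;
}

// Delay-and-sum with nearest-sample extraction: for each focal point,
// I = sum_t sum_r RF(t, r, n*) where n* is the sample whose receive time is
// nearest to the two-way time of flight (ties at half a sample round away
// from zero). Out-of-range delays contribute zero.
//
// tx: T x 2 transmit origins (mm); rxm: K x 2 receive centers (mm);
// focal: F x 2 focal points (mm); rf laid out [T x K x N] column-major.
// [[Rcpp::export]]
NumericVector das_kernel(NumericVector rf, int T, int K, int N,
                         NumericMatrix tx, NumericMatrix rxm,
                         NumericMatrix focal,
                         double fs, double t0, double c_mm) {
  const int F = focal.nrow();
  NumericVector out(F);
  std::vector<double> drx(K);
  for (int f = 0; f < F; ++f) {
    const double xf = focal(f, 0), zf = focal(f, 1);
    for (int r = 0; r < K; ++r) {
      const double dx = xf - rxm(r, 0), dz = zf - rxm(r, 1);
      drx[r] = std::sqrt(dx * dx + dz * dz);
    }
    double acc = 0.0;
    for (int t = 0; t < T; ++t) {
      const double dx = xf - tx(t, 0), dz = zf - tx(t, 1);
      const double dtx = std::sqrt(dx * dx + dz * dz);
      for (int r = 0; r < K; ++r) {
        const double nn = ((dtx + drx[r]) / c_mm - t0) * fs;
        const double nr = (nn >= 0.0) ? std::floor(nn + 0.5)
                                      : std::ceil(nn - 0.5);
        const int n = (int)nr;
        if (n >= 0 && n < N)
          acc += rf[(R_xlen_t)t + (R_xlen_t)T * r + (R_xlen_t)T * K * n];
      }
    }
    out[f] = acc;
  }
  return out;
}
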