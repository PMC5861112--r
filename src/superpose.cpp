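#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Spherical-wave superposition kernel (see R/acoustic.R for the model
// description): every voxel is an equal-volume spherical source whose
// closed-form bipolar N-wave, convolved with a box over the voxel's
// radial footprint, is evaluated at the sample times t_k = k dt and
// accumulated per detector point. Sample k (1-based) corresponds to
// time k*dt.

// [[Rcpp::export(name = ".superpose_cpp")]]
NumericMatrix superpose(NumericVector p0, IntegerVector dims, double h,
                        NumericVector x0, NumericVector y0, NumericVector z0,
                        NumericMatrix pts, double v, double dt, int nbins) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int npts = pts.nrow();
  NumericMatrix out(npts, nbins);
  const double a_v = h * std::cbrt(3.0 / (4.0 * M_PI));
  const double a_eff = std::max(a_v, 0.55 * v * dt);
  const double scale = (h * h * h) / ((4.0 / 3.0) * M_PI * a_eff * a_eff * a_eff);

  for (int e = 0; e < npts; ++e) {
    const double px = pts(e, 0), py = pts(e, 1), pz = pts(e, 2);
    R_xlen_t idx = 0;
    for (int iz = 0; iz < nz; ++iz) {
      const double dz = z0[iz] - pz;
      for (int iy = 0; iy < ny; ++iy) {
        const double dy = y0[iy] - py;
        for (int ix = 0; ix < nx; ++ix, ++idx) {
          const double q = p0[idx];
          if (q == 0.0) continue;
          const double dx = x0[ix] - px;
          const double r = std::sqrt(dx * dx + dy * dy + dz * dz);
          double delta = h * (std::fabs(dx) + std::fabs(dy) + std::fabs(dz)) /
                         std::max(r, h / 2.0);
          if (delta < 1e-9) delta = 1e-9;
          const double amp = q * scale;
          const double half = a_eff + delta / 2.0;
          int k = (int)std::ceil((r - half) / (v * dt));
          const int kend = (int)std::floor((r + half) / (v * dt));
          if (k < 1) k = 1;
          for (; k <= kend && k <= nbins; ++k) {
            const double u = r - v * k * dt;
            double A = u - delta / 2.0, B = u + delta / 2.0;
            if (A < -a_eff) A = -a_eff;
            if (B > a_eff) B = a_eff;
            if (B > A)
              out(e, k - 1) += amp * (B * B - A * A) / (4.0 * r * delta);
          }
        }
      }
    }
  }
  return out;
}
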