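#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Weighted local polynomial fit over a fixed voxel footprint, evaluated at
// every foreground voxel of a 3D volume.
//
// re, im  : real and imaginary payload (im of length 0 for real volumes)
// dims    : volume dimensions (x, y, z)
// fg      : foreground mask; background voxels never contribute and yield NA
// ref     : reference volume for anatomical adaptation (length 0 = none)
// sscale  : Gaussian intensity scale s = w * range(ref over foreground);
//           <= 0 disables adaptation
// offsets : n x 3 integer voxel offsets of the footprint
// X       : n x p monomial design in physical metres, rows parallel offsets;
//           column order 1, x, y, z, x^2, y^2, z^2, xy, xz, yz (degree 2)
//           or just the constant column (degree 0)
// want    : 0 = smoothed value (a0), 1 = gradient (a_x, a_y, a_z),
//           2 = Laplacian 2*(a_xx + a_yy + a_zz)
//
// Voxels whose fit has fewer contributing neighbours than monomials, or a
// numerically singular normal system, are returned as NA (unreconstructable).
// [[Rcpp::export]]
List sg_fit_cpp(NumericVector re, NumericVector im, IntegerVector dims,
                LogicalVector fg, NumericVector ref, double sscale,
                IntegerMatrix offsets, NumericMatrix X, int want) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  const int noff = offsets.nrow();
  const int p = X.ncol();
  const bool has_im = im.size() > 0;
  const bool adapt = ref.size() > 0 && sscale > 0.0;
  const double inv2s2 = adapt ? 1.0 / (2.0 * sscale * sscale) : 0.0;

  const int nout = (want == 1) ? 3 : 1;
  std::vector<NumericVector> out_re(nout), out_im;
  for (int q = 0; q < nout; ++q)
    out_re[q] = NumericVector(nvox, NA_REAL);
  if (has_im) {
    out_im.resize(nout);
    for (int q = 0; q < nout; ++q)
      out_im[q] = NumericVector(nvox, NA_REAL);
  }

  arma::mat G(p, p);
  arma::mat rhs(p, has_im ? 2 : 1);
  arma::mat coef;
  arma::rowvec xrow(p);

  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const R_xlen_t idx = (R_xlen_t)i + nx * ((R_xlen_t)j + (R_xlen_t)ny * k);
        if (!fg[idx]) continue;
        const double r0 = adapt ? ref[idx] : 0.0;
        G.zeros();
        rhs.zeros();
        int cnt = 0;
        for (int o = 0; o < noff; ++o) {
          const int ii = i + offsets(o, 0);
          const int jj = j + offsets(o, 1);
          const int kk = k + offsets(o, 2);
          if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
            continue;
          const R_xlen_t oidx =
            (R_xlen_t)ii + nx * ((R_xlen_t)jj + (R_xlen_t)ny * kk);
          if (!fg[oidx]) continue;
          const double vre = re[oidx];
          if (ISNAN(vre)) continue;
          double w = 1.0;
          if (adapt) {
            const double d = ref[oidx] - r0;
            w = std::exp(-d * d * inv2s2);
          }
          if (w < 1e-300) continue;
          ++cnt;
          for (int c = 0; c < p; ++c) xrow[c] = X(o, c);
          // G += w * x x', rhs += w * x * value (upper triangle only)
          for (int a = 0; a < p; ++a) {
            const double wxa = w * xrow[a];
            for (int b = a; b < p; ++b) G(a, b) += wxa * xrow[b];
            rhs(a, 0) += wxa * vre;
            if (has_im) rhs(a, 1) += wxa * im[oidx];
          }
        }
        if (cnt < p) continue;   // underdetermined -> unreconstructable
        G = arma::symmatu(G);
        bool ok = arma::solve(coef, G, rhs,
                              arma::solve_opts::likely_sympd +
                              arma::solve_opts::no_approx);
        if (!ok || !coef.is_finite()) continue;
        if (want == 0) {
          out_re[0][idx] = coef(0, 0);
          if (has_im) out_im[0][idx] = coef(0, 1);
        } else if (want == 1) {
          for (int q = 0; q < 3; ++q) {
            out_re[q][idx] = coef(q + 1, 0);
            if (has_im) out_im[q][idx] = coef(q + 1, 1);
          }
        } else {
          out_re[0][idx] = 2.0 * (coef(4, 0) + coef(5, 0) + coef(6, 0));
          if (has_im)
            out_im[0][idx] = 2.0 * (coef(4, 1) + coef(5, 1) + coef(6, 1));
        }
      }

  List res;
  if (want == 1) {
    res["gx_re"] = out_re[0]; res["gy_re"] = out_re[1]; res["gz_re"] = out_re[2];
    if (has_im) {
      res["gx_im"] = out_im[0]; res["gy_im"] = out_im[1]; res["gz_im"] = out_im[2];
    }
  } else {
    res["val_re"] = out_re[0];
    if (has_im) res["val_im"] = out_im[0];
  }
  return res;
}
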