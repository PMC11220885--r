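#include <Rcpp.h>
using namespace Rcpp;

// Direct Gaussian-atom structure-factor summation:
//   F(q) = exp(-2 pi^2 sigma^2 |q|^2) * sum_j w_j exp(-2 pi i q . r_j)
// Exact for the Gaussian-atom density model; cost O(n_atoms * n_q).
// [[Rcpp::export]]
ComplexVector cpp_structure_factor(const NumericMatrix& xyz,
                                   const NumericVector& w,
                                   const NumericMatrix& q,
                                   double sigma) {
  const int na = xyz.nrow(), nq = q.nrow();
  ComplexVector out(nq);
  const double twopi = 2.0 * M_PI;
  const double damp = 2.0 * M_PI * M_PI * sigma * sigma;
  for (int k = 0; k < nq; ++k) {
    const double qx = q(k, 0), qy = q(k, 1), qz = q(k, 2);
    const double env = std::exp(-damp * (qx * qx + qy * qy + qz * qz));
    double re = 0.0, im = 0.0;
    for (int j = 0; j < na; ++j) {
      const double ph = -twopi * (qx * xyz(j, 0) + qy * xyz(j, 1) + qz * xyz(j, 2));
      re += w[j] * std::cos(ph);
      im += w[j] * std::sin(ph);
    }
    out[k].r = env * re;
    out[k].i = env * im;
  }
  return out;
}

// Trilinear interpolation of a 3D array at fractional (1-based) voxel
// coordinates. Points outside the grid, or touching an NA voxel, give NA.
// [[Rcpp::export]]
NumericVector cpp_trilinear_gather(const NumericVector& vol,
                                   const IntegerVector& dim,
                                   const NumericMatrix& pts) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const int n = pts.nrow();
  NumericVector out(n);
  const double* v = vol.begin();
  for (int i = 0; i < n; ++i) {
    double x = pts(i, 0), y = pts(i, 1), z = pts(i, 2);
    if (!(x >= 1.0 && x <= d1 && y >= 1.0 && y <= d2 && z >= 1.0 && z <= d3)) {
      out[i] = NA_REAL;
      continue;
    }
    int x0 = (int)std::floor(x); if (x0 == d1) x0 = d1 - 1;
    int y0 = (int)std::floor(y); if (y0 == d2) y0 = d2 - 1;
    int z0 = (int)std::floor(z); if (z0 == d3) z0 = d3 - 1;
    const double fx = x - x0, fy = y - y0, fz = z - z0;
    double acc = 0.0;
    bool bad = false;
    for (int dz = 0; dz <= 1 && !bad; ++dz)
      for (int dy = 0; dy <= 1 && !bad; ++dy)
        for (int dx = 0; dx <= 1 && !bad; ++dx) {
          const double wt = (dx ? fx : 1.0 - fx) * (dy ? fy : 1.0 - fy) * (dz ? fz : 1.0 - fz);
          if (wt == 0.0) continue;
          const double val = v[(size_t)(x0 - 1 + dx)
                              + (size_t)d1 * (y0 - 1 + dy)
                              + (size_t)d1 * d2 * (z0 - 1 + dz)];
          if (ISNAN(val)) { bad = true; break; }
          acc += wt * val;
        }
    out[i] = bad ? NA_REAL : acc;
  }
  return out;
}

// Trilinear scatter (deposit): each value is spread over the 8 voxels
// surrounding its fractional (1-based) coordinate with trilinear weights.
// Returns the accumulated value sum and weight sum arrays.
// [[Rcpp::export]]
List cpp_trilinear_scatter(const IntegerVector& dim,
                           const NumericMatrix& pts,
                           const NumericVector& val) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const size_t ntot = (size_t)d1 * d2 * d3;
  NumericVector acc((R_xlen_t)ntot), wt((R_xlen_t)ntot);
  const int n = pts.nrow();
  for (int i = 0; i < n; ++i) {
    const double a = val[i];
    if (ISNAN(a)) continue;
    double x = pts(i, 0), y = pts(i, 1), z = pts(i, 2);
    if (!(x >= 1.0 && x <= d1 && y >= 1.0 && y <= d2 && z >= 1.0 && z <= d3)) continue;
    int x0 = (int)std::floor(x); if (x0 == d1) x0 = d1 - 1;
    int y0 = (int)std::floor(y); if (y0 == d2) y0 = d2 - 1;
    int z0 = (int)std::floor(z); if (z0 == d3) z0 = d3 - 1;
    const double fx = x - x0, fy = y - y0, fz = z - z0;
    for (int dz = 0; dz <= 1; ++dz)
      for (int dy = 0; dy <= 1; ++dy)
        for (int dx = 0; dx <= 1; ++dx) {
          const double w = (dx ? fx : 1.0 - fx) * (dy ? fy : 1.0 - fy) * (dz ? fz : 1.0 - fz);
          if (w == 0.0) continue;
          const size_t idx = (size_t)(x0 - 1 + dx)
                           + (size_t)d1 * (y0 - 1 + dy)
                           + (size_t)d1 * d2 * (z0 - 1 + dz);
          acc[idx] += w * a;
          wt[idx] += w;
        }
  }
  return List::create(_["sum"] = acc, _["weight"] = wt);
}

// Bilinear interpolation of a matrix at fractional (1-based) coordinates;
// NA outside or when touching an NA pixel.
// [[Rcpp::export]]
NumericVector cpp_bilinear_gather(const NumericMatrix& img,
                                  const NumericMatrix& pts) {
  const int d1 = img.nrow(), d2 = img.ncol();
  const int n = pts.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double x = pts(i, 0), y = pts(i, 1);
    if (!(x >= 1.0 && x <= d1 && y >= 1.0 && y <= d2)) {
      out[i] = NA_REAL;
      continue;
    }
    int x0 = (int)std::floor(x); if (x0 == d1) x0 = d1 - 1;
    int y0 = (int)std::floor(y); if (y0 == d2) y0 = d2 - 1;
    const double fx = x - x0, fy = y - y0;
    double acc = 0.0;
    bool bad = false;
    for (int dy = 0; dy <= 1 && !bad; ++dy)
      for (int dx = 0; dx <= 1 && !bad; ++dx) {
        const double w = (dx ? fx : 1.0 - fx) * (dy ? fy : 1.0 - fy);
        if (w == 0.0) continue;
        const double v = img(x0 - 1 + dx, y0 - 1 + dy);
        if (ISNAN(v)) { bad = true; break; }
        acc += w * v;
      }
    out[i] = bad ? NA_REAL : acc;
  }
  return out;
}
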