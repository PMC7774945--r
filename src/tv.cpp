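// Total-variation primitives on 3D volumes (backward differences; first
// index of each axis has difference 0), with the smoothed gradient
// magnitude sqrt(. + eps) used by the steepest-descent TV step.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {
inline R_xlen_t lin(int i, int j, int k, int nx, int ny) {
  return (R_xlen_t)i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
}
}  // namespace

// [[Rcpp::export]]
double cpp_tv_norm(NumericVector v, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double *p = v.begin();
  double acc = 0.0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const double c = p[lin(i, j, k, nx, ny)];
        const double dx = i > 0 ? c - p[lin(i - 1, j, k, nx, ny)] : 0.0;
        const double dy = j > 0 ? c - p[lin(i, j - 1, k, nx, ny)] : 0.0;
        const double dz = k > 0 ? c - p[lin(i, j, k - 1, nx, ny)] : 0.0;
        acc += std::sqrt(dx * dx + dy * dy + dz * dz);
      }
  return acc;
}

// n_inner steepest-descent steps on the voxelwise-normalised TV gradient
// (descent field of unit per-voxel magnitude), each scaled by `step`.
// [[Rcpp::export]]
NumericVector cpp_tv_descent(NumericVector v, IntegerVector dims,
                             double step, int n_inner, double eps) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out = clone(v);
  double *p = out.begin();
  const R_xlen_t n = out.size();
  std::vector<double> tx(n), ty(n), tz(n), g(n);
  for (int it = 0; it < n_inner; ++it) {
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          const R_xlen_t c = lin(i, j, k, nx, ny);
          const double dx = i > 0 ? p[c] - p[lin(i - 1, j, k, nx, ny)] : 0.0;
          const double dy = j > 0 ? p[c] - p[lin(i, j - 1, k, nx, ny)] : 0.0;
          const double dz = k > 0 ? p[c] - p[lin(i, j, k - 1, nx, ny)] : 0.0;
          const double m = std::sqrt(dx * dx + dy * dy + dz * dz + eps);
          tx[c] = dx / m; ty[c] = dy / m; tz[c] = dz / m;
        }
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          const R_xlen_t c = lin(i, j, k, nx, ny);
          double acc = tx[c] + ty[c] + tz[c];
          if (i + 1 < nx) acc -= tx[lin(i + 1, j, k, nx, ny)];
          if (j + 1 < ny) acc -= ty[lin(i, j + 1, k, nx, ny)];
          if (k + 1 < nz) acc -= tz[lin(i, j, k + 1, nx, ny)];
          g[c] = acc;
        }
    for (R_xlen_t c = 0; c < n; ++c) {
      const double m = std::sqrt(g[c] * g[c] + eps);
      p[c] -= step * g[c] / m;
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_tv_gradient(NumericVector v, IntegerVector dims,
                              double eps) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double *p = v.begin();
  const R_xlen_t n = v.size();
  // per-voxel backward differences over smoothed magnitude
  std::vector<double> tx(n), ty(n), tz(n);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const R_xlen_t c = lin(i, j, k, nx, ny);
        const double dx = i > 0 ? p[c] - p[lin(i - 1, j, k, nx, ny)] : 0.0;
        const double dy = j > 0 ? p[c] - p[lin(i, j - 1, k, nx, ny)] : 0.0;
        const double dz = k > 0 ? p[c] - p[lin(i, j, k - 1, nx, ny)] : 0.0;
        const double m = std::sqrt(dx * dx + dy * dy + dz * dz + eps);
        tx[c] = dx / m; ty[c] = dy / m; tz[c] = dz / m;
      }
  NumericVector g(n);
  double *pg = g.begin();
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const R_xlen_t c = lin(i, j, k, nx, ny);
        double acc = tx[c] + ty[c] + tz[c];
        if (i + 1 < nx) acc -= tx[lin(i + 1, j, k, nx, ny)];
        if (j + 1 < ny) acc -= ty[lin(i, j + 1, k, nx, ny)];
        if (k + 1 < nz) acc -= tz[lin(i, j, k + 1, nx, ny)];
        pg[c] = acc;
      }
  return g;
}
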