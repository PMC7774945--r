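// Linear-sweep tomosynthesis projector.
//
// Geometry convention (all mm): isocenter at the origin; the source moves
// along x at height z = +sid, with per-view position x_s = sid * tan(theta);
// the detector is stationary in the plane z = -(sdd - sid), pixel centres at
// u = (iu + 0.5 - nu/2) * pitch (along x) and v likewise (along y).
// Voxel (i,j,k), 0-based, spans [x0 + i*sx, x0 + (i+1)*sx) etc. with
// x0 = -nx*sx/2. Ray integrals use exact voxel-intersection lengths
// (Siddon/Amanatides-Woo traversal); values are accumulated in cm so that a
// volume in 1/cm yields dimensionless line integrals.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct Grid {
  int nx, ny, nz;
  double sx, sy, sz;
  double x0, y0, z0;
};

template <class Visit>
inline void traverse_ray(const Grid &g, double px, double py, double pz,
                         double qx, double qy, double qz, Visit &&visit) {
  const double dx = qx - px, dy = qy - py, dz = qz - pz;
  const double raylen = std::sqrt(dx * dx + dy * dy + dz * dz);
  if (raylen <= 0) return;
  const double d[3] = {dx, dy, dz};
  const double p[3] = {px, py, pz};
  const double lo[3] = {g.x0, g.y0, g.z0};
  const double hi[3] = {g.x0 + g.nx * g.sx, g.y0 + g.ny * g.sy,
                        g.z0 + g.nz * g.sz};
  double tmin = 0.0, tmax = 1.0;
  for (int a = 0; a < 3; ++a) {
    if (std::fabs(d[a]) < 1e-12) {
      if (p[a] <= lo[a] || p[a] >= hi[a]) return;
    } else {
      double t1 = (lo[a] - p[a]) / d[a];
      double t2 = (hi[a] - p[a]) / d[a];
      if (t1 > t2) std::swap(t1, t2);
      if (t1 > tmin) tmin = t1;
      if (t2 < tmax) tmax = t2;
    }
  }
  if (tmax - tmin < 1e-12) return;

  const double sp[3] = {g.sx, g.sy, g.sz};
  const int n[3] = {g.nx, g.ny, g.nz};
  int idx[3], step[3];
  double tdelta[3], tnext[3];
  const double eps = 1e-10;
  for (int a = 0; a < 3; ++a) {
    double start = p[a] + (tmin + eps) * d[a];
    int i = (int)std::floor((start - lo[a]) / sp[a]);
    if (i < 0) i = 0;
    if (i > n[a] - 1) i = n[a] - 1;
    idx[a] = i;
    if (std::fabs(d[a]) < 1e-12) {
      step[a] = 0;
      tdelta[a] = std::numeric_limits<double>::infinity();
      tnext[a] = std::numeric_limits<double>::infinity();
    } else {
      step[a] = d[a] > 0 ? 1 : -1;
      tdelta[a] = sp[a] / std::fabs(d[a]);
      double bound = lo[a] + (idx[a] + (step[a] > 0 ? 1 : 0)) * sp[a];
      tnext[a] = (bound - p[a]) / d[a];
    }
  }
  double tcur = tmin;
  while (tcur < tmax - 1e-12) {
    int amin = 0;
    if (tnext[1] < tnext[amin]) amin = 1;
    if (tnext[2] < tnext[amin]) amin = 2;
    double tstop = tnext[amin] < tmax ? tnext[amin] : tmax;
    double len = (tstop - tcur) * raylen;  // mm
    if (len > 0) {
      R_xlen_t lin = (R_xlen_t)idx[0] +
                     (R_xlen_t)g.nx * (idx[1] + (R_xlen_t)g.ny * idx[2]);
      visit(lin, len);
    }
    if (tstop >= tmax - 1e-12) break;
    idx[amin] += step[amin];
    if (idx[amin] < 0 || idx[amin] >= n[amin]) break;
    tnext[amin] += tdelta[amin];
    tcur = tstop;
  }
}

inline Grid make_grid(const IntegerVector &dims, const NumericVector &spacing) {
  Grid g;
  g.nx = dims[0]; g.ny = dims[1]; g.nz = dims[2];
  g.sx = spacing[0]; g.sy = spacing[1]; g.sz = spacing[2];
  g.x0 = -0.5 * g.nx * g.sx;
  g.y0 = -0.5 * g.ny * g.sy;
  g.z0 = -0.5 * g.nz * g.sz;
  return g;
}

}  // namespace

// [[Rcpp::export]]
NumericVector cpp_forward_project(NumericVector vol, IntegerVector dims,
                                  NumericVector spacing, double sid,
                                  double sdd, NumericVector angles_rad,
                                  int nu, int nv, double pitch) {
  Grid g = make_grid(dims, spacing);
  const int nviews = angles_rad.size();
  NumericVector out((R_xlen_t)nu * nv * nviews);
  const double *v = vol.begin();
  const double zdet = -(sdd - sid);
  for (int a = 0; a < nviews; ++a) {
    const double sx = sid * std::tan(angles_rad[a]);
    for (int iv = 0; iv < nv; ++iv) {
      const double vy = (iv + 0.5 - 0.5 * nv) * pitch;
      for (int iu = 0; iu < nu; ++iu) {
        const double ux = (iu + 0.5 - 0.5 * nu) * pitch;
        double sum = 0.0;
        traverse_ray(g, sx, 0.0, sid, ux, vy, zdet,
                     [&](R_xlen_t lin, double len) { sum += v[lin] * len; });
        out[(R_xlen_t)iu + (R_xlen_t)nu * (iv + (R_xlen_t)nv * a)] =
            sum * 0.1;  // mm -> cm
      }
    }
  }
  return out;
}

// Total intersection length of each ray with the volume box (cm); this equals
// the per-ray sum of system-matrix weights used by the SART normalisation.
// [[Rcpp::export]]
NumericVector cpp_chord_length(IntegerVector dims, NumericVector spacing,
                               double sid, double sdd,
                               NumericVector angles_rad, int nu, int nv,
                               double pitch) {
  Grid g = make_grid(dims, spacing);
  const int nviews = angles_rad.size();
  NumericVector out((R_xlen_t)nu * nv * nviews);
  const double zdet = -(sdd - sid);
  for (int a = 0; a < nviews; ++a) {
    const double sx = sid * std::tan(angles_rad[a]);
    for (int iv = 0; iv < nv; ++iv) {
      const double vy = (iv + 0.5 - 0.5 * nv) * pitch;
      for (int iu = 0; iu < nu; ++iu) {
        const double ux = (iu + 0.5 - 0.5 * nu) * pitch;
        double sum = 0.0;
        traverse_ray(g, sx, 0.0, sid, ux, vy, zdet,
                     [&](R_xlen_t, double len) { sum += len; });
        out[(R_xlen_t)iu + (R_xlen_t)nu * (iv + (R_xlen_t)nv * a)] =
            sum * 0.1;
      }
    }
  }
  return out;
}

// Length-weighted backprojection: num[j] = sum_i a_ij * value_i,
// den[j] = sum_i a_ij (weights in cm). The exact adjoint of
// cpp_forward_project.
// [[Rcpp::export]]
List cpp_backproject(NumericVector values, IntegerVector dims,
                     NumericVector spacing, double sid, double sdd,
                     NumericVector angles_rad, int nu, int nv, double pitch) {
  Grid g = make_grid(dims, spacing);
  const int nviews = angles_rad.size();
  R_xlen_t nvox = (R_xlen_t)g.nx * g.ny * g.nz;
  NumericVector num(nvox), den(nvox);
  double *pn = num.begin(), *pd = den.begin();
  const double zdet = -(sdd - sid);
  for (int a = 0; a < nviews; ++a) {
    const double sx = sid * std::tan(angles_rad[a]);
    for (int iv = 0; iv < nv; ++iv) {
      const double vy = (iv + 0.5 - 0.5 * nv) * pitch;
      for (int iu = 0; iu < nu; ++iu) {
        const double ux = (iu + 0.5 - 0.5 * nu) * pitch;
        const double val =
            values[(R_xlen_t)iu + (R_xlen_t)nu * (iv + (R_xlen_t)nv * a)];
        traverse_ray(g, sx, 0.0, sid, ux, vy, zdet,
                     [&](R_xlen_t lin, double len) {
                       pn[lin] += val * len * 0.1;
                       pd[lin] += len * 0.1;
                     });
      }
    }
  }
  return List::create(_["num"] = num, _["den"] = den);
}
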