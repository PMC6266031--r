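#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Exact voxel traversal of a ray through a regular grid (Amanatides-Woo
// stepping with midpoint voxel identification, which realises the half-open
// [lower, upper) voxel convention without corner-case double counting).
//
// p: ray origin (mm), d: unit direction. Grid origin is the corner of voxel
// (0,0,0). Returns 0-based voxel indices, per-voxel geometric lengths, the
// cumulative WEPL prefix sum and the breakpoint parameters t (distance from
// p, mm) of each segment end, plus the entry/exit parameters.
// [[Rcpp::export]]
List raytrace_wepl_cpp(IntegerVector dims, NumericVector spacing,
                       NumericVector origin, NumericVector rsp,
                       NumericVector p, NumericVector d) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  double tmin = -1e300, tmax = 1e300;
  // slab clipping
  for (int a = 0; a < 3; ++a) {
    const double lo = origin[a], hi = origin[a] + dims[a] * spacing[a];
    if (std::fabs(d[a]) < 1e-14) {
      if (p[a] < lo || p[a] >= hi) return List::create(_["n"] = 0);
    } else {
      double t0 = (lo - p[a]) / d[a], t1 = (hi - p[a]) / d[a];
      if (t0 > t1) std::swap(t0, t1);
      if (t0 > tmin) tmin = t0;
      if (t1 < tmax) tmax = t1;
    }
  }
  if (tmin >= tmax) return List::create(_["n"] = 0);
  if (tmin < 0) tmin = 0.0;  // origin inside grid
  if (tmax <= tmin) return List::create(_["n"] = 0);

  const double eps = 1e-9 * (tmax - tmin + 1.0);
  std::vector<int> vx, vy, vz;
  std::vector<double> len, tend;
  double t = tmin;
  int guard = 4 * (nx + ny + nz) + 8;
  while (t < tmax - eps && guard-- > 0) {
    // next boundary crossing along each axis
    double tn = tmax;
    for (int a = 0; a < 3; ++a) {
      if (std::fabs(d[a]) < 1e-14) continue;
      const double pos = p[a] + t * d[a];
      double f = (pos - origin[a]) / spacing[a];
      double bnd = (d[a] > 0) ? (std::floor(f + 1e-9) + 1.0)
                              : (std::ceil(f - 1e-9) - 1.0);
      double ta = (origin[a] + bnd * spacing[a] - p[a]) / d[a];
      if (ta > t + eps && ta < tn) tn = ta;
    }
    if (tn <= t + eps) tn = std::min(t + eps * 10, tmax);
    const double tm = 0.5 * (t + tn);
    int ix = (int)std::floor((p[0] + tm * d[0] - origin[0]) / spacing[0]);
    int iy = (int)std::floor((p[1] + tm * d[1] - origin[1]) / spacing[1]);
    int iz = (int)std::floor((p[2] + tm * d[2] - origin[2]) / spacing[2]);
    if (ix >= 0 && ix < nx && iy >= 0 && iy < ny && iz >= 0 && iz < nz) {
      vx.push_back(ix); vy.push_back(iy); vz.push_back(iz);
      len.push_back(tn - t); tend.push_back(tn);
    }
    t = tn;
  }
  const int n = (int)vx.size();
  IntegerMatrix vox(n, 3);
  NumericVector l(n), w(n), te(n);
  double cum = 0.0;
  for (int i = 0; i < n; ++i) {
    vox(i, 0) = vx[i]; vox(i, 1) = vy[i]; vox(i, 2) = vz[i];
    l[i] = len[i];
    const R_xlen_t lin = (R_xlen_t)vx[i] + (R_xlen_t)nx * (vy[i] + (R_xlen_t)ny * vz[i]);
    cum += len[i] * rsp[lin];
    w[i] = cum;
    te[i] = tend[i];
  }
  return List::create(_["n"] = n, _["vox"] = vox, _["length"] = l,
                      _["wepl"] = w, _["t_end"] = te,
                      _["t_entry"] = tmin, _["t_exit"] = tmax);
}
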