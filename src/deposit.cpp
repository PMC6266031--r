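#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double TWO_PI = 6.283185307179586;

// Deposit one (sub-)pencil beam onto the dose grid.
//
// Axis: point A (t = 0) + unit direction d. The radiological depth along the
// axis is supplied as a uniformly sampled water-equivalent-path-length table
// wepl[k] at t = k*wdt (piecewise linear, 0 before the first sample, constant
// after the last). Depth-dependent beam data come as a matrix with columns
//   0 idd, 1 s1, 2 s2, 3 s3, 4 w1, 5 w2, 6 w3, 7 let, 8 alpha, 9 sqrtbeta,
//   10 zstar
// on a uniform depth grid of step dz (water-equivalent mm).
//
// sigma_air is composed in quadrature onto every Gaussian component, as is
// the range-shifter term theta*(air_gap + max(t - t_skin, 0)). Beyond the
// tabulated depth the integrated depth dose is zero and nothing is scored.
//
// Scoring: either into the five full-length arrays (dose and the four
// dose-weighted accumulators), or, when subset_map/subset_out are given,
// into the compact row matrix (columns dose, d*let, d*alpha, d*sqrtbeta,
// d*zstar) used to build spot-influence matrices.
// [[Rcpp::export]]
void deposit_spot_cpp(IntegerVector dims, NumericVector spacing,
                      NumericVector origin, NumericVector A, NumericVector d,
                      NumericVector wepl, double wdt, double t_skin,
                      double t_exit, NumericMatrix tab, double dz,
                      double n_eff, double sigma_air, double theta,
                      double air_gap, double rs_wet, double cutoff,
                      double rmax, NumericVector dose, NumericVector slet,
                      NumericVector salpha, NumericVector ssqb,
                      NumericVector szstar,
                      Nullable<IntegerVector> subset_map = R_NilValue,
                      Nullable<NumericMatrix> subset_out = R_NilValue) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int ndep = tab.nrow(), nw = wepl.size();
  const double sa2 = sigma_air * sigma_air;
  const bool sub = subset_map.isNotNull();
  IntegerVector smap;
  NumericMatrix sout;
  if (sub) { smap = subset_map.get(); sout = subset_out.get(); }

  // bounding box around the axis segment [0, t_exit], expanded by rmax
  int lo[3], hi[3];
  for (int a = 0; a < 3; ++a) {
    double e0 = A[a], e1 = A[a] + t_exit * d[a];
    double mn = std::min(e0, e1) - rmax, mx = std::max(e0, e1) + rmax;
    lo[a] = (int)std::floor((mn - origin[a]) / spacing[a] - 0.5);
    hi[a] = (int)std::ceil((mx - origin[a]) / spacing[a] - 0.5);
    if (lo[a] < 0) lo[a] = 0;
    if (hi[a] > dims[a] - 1) hi[a] = dims[a] - 1;
    if (lo[a] > hi[a]) return;
  }
  const double rmax2 = rmax * rmax;

  for (int iz = lo[2]; iz <= hi[2]; ++iz) {
    const double cz = origin[2] + (iz + 0.5) * spacing[2] - A[2];
    for (int iy = lo[1]; iy <= hi[1]; ++iy) {
      const double cy = origin[1] + (iy + 0.5) * spacing[1] - A[1];
      const R_xlen_t base = (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz);
      for (int ix = lo[0]; ix <= hi[0]; ++ix) {
        const double cx = origin[0] + (ix + 0.5) * spacing[0] - A[0];
        const double t = cx * d[0] + cy * d[1] + cz * d[2];
        double r2 = cx * cx + cy * cy + cz * cz - t * t;
        if (r2 < 0) r2 = 0;
        if (r2 > rmax2) continue;
        // radiological depth
        double w;
        if (t <= 0) {
          w = 0.0;
        } else {
          const double k = t / wdt;
          const int k0 = (int)k;
          if (k0 >= nw - 1) w = wepl[nw - 1];
          else w = wepl[k0] + (k - k0) * (wepl[k0 + 1] - wepl[k0]);
        }
        const double zw = w + rs_wet;
        const double fz = zw / dz;
        const int j = (int)fz;
        if (j >= ndep - 1) continue;  // beyond table: idd = 0
        const double fr = fz - j;
        const double idd = tab(j, 0) + fr * (tab(j + 1, 0) - tab(j, 0));
        if (idd <= 0) continue;
        // range-shifter widening grows with geometric depth in the patient
        double srs = 0.0;
        if (theta > 0) {
          double dg = t - t_skin;
          if (dg < 0) dg = 0;
          srs = theta * (air_gap + dg);
        }
        const double extra = sa2 + srs * srs;
        const double s3t = tab(j, 3) + fr * (tab(j + 1, 3) - tab(j, 3));
        const double s3c2 = s3t * s3t + extra;
        if (r2 > cutoff * cutoff * s3c2) continue;
        const double s1t = tab(j, 1) + fr * (tab(j + 1, 1) - tab(j, 1));
        const double s2t = tab(j, 2) + fr * (tab(j + 1, 2) - tab(j, 2));
        const double w1 = tab(j, 4) + fr * (tab(j + 1, 4) - tab(j, 4));
        const double w2 = tab(j, 5) + fr * (tab(j + 1, 5) - tab(j, 5));
        const double w3 = tab(j, 6) + fr * (tab(j + 1, 6) - tab(j, 6));
        const double v1 = s1t * s1t + extra, v2 = s2t * s2t + extra;
        const double L = w1 / (TWO_PI * v1) * std::exp(-r2 / (2.0 * v1)) +
                         w2 / (TWO_PI * v2) * std::exp(-r2 / (2.0 * v2)) +
                         w3 / (TWO_PI * s3c2) * std::exp(-r2 / (2.0 * s3c2));
        const double dc = n_eff * idd * L;
        if (dc <= 0) continue;
        const double let = tab(j, 7) + fr * (tab(j + 1, 7) - tab(j, 7));
        const double alp = tab(j, 8) + fr * (tab(j + 1, 8) - tab(j, 8));
        const double sqb = tab(j, 9) + fr * (tab(j + 1, 9) - tab(j, 9));
        const double zst = tab(j, 10) + fr * (tab(j + 1, 10) - tab(j, 10));
        const R_xlen_t lin = base + ix;
        if (sub) {
          const int row = smap[lin];
          if (row < 0) continue;
          sout(row, 0) += dc;
          sout(row, 1) += dc * let;
          sout(row, 2) += dc * alp;
          sout(row, 3) += dc * sqb;
          sout(row, 4) += dc * zst;
        } else {
          dose[lin] += dc;
          slet[lin] += dc * let;
          salpha[lin] += dc * alp;
          ssqb[lin] += dc * sqb;
          szstar[lin] += dc * zst;
        }
      }
    }
  }
}
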