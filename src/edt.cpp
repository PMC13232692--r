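#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// 1D squared-distance transform (lower envelope of parabolas) with sampling
// step w.  f holds squared distances and may contain +Inf.
static void dt1d(const std::vector<double> &f, double w,
                 std::vector<double> &d) {
  const double INF = std::numeric_limits<double>::infinity();
  int n = (int)f.size();
  d.assign(n, INF);
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = -1;
  for (int q = 0; q < n; ++q) {
    if (f[q] == INF) continue;
    if (k < 0) {
      k = 0; v[0] = q; z[0] = -INF; z[1] = INF;
      continue;
    }
    double s = 0.0;
    while (k >= 0) {
      double qq = q * w, vv = v[k] * w;
      s = ((f[q] + qq * qq) - (f[v[k]] + vv * vv)) / (2.0 * (qq - vv));
      if (s <= z[k]) --k; else break;
    }
    if (k < 0) {
      k = 0; v[0] = q; z[0] = -INF; z[1] = INF;
    } else {
      ++k; v[k] = q; z[k] = s; z[k + 1] = INF;
    }
  }
  if (k < 0) return;  // no finite parabola: all Inf
  int j = 0;
  for (int q = 0; q < n; ++q) {
    double qq = q * w;
    while (z[j + 1] < qq) ++j;
    double diff = qq - v[j] * w;
    d[q] = diff * diff + f[v[j]];
  }
}

// Exact anisotropic Euclidean distance transform: for each voxel the
// distance (mm) to the nearest nonzero voxel of `mask`; dims = (n1, n2, n3)
// in array order (first index fastest), spacing = per-axis step in mm.
// [[Rcpp::export(name = ".edt3d")]]
NumericVector edt3d(LogicalVector mask, IntegerVector dims,
                    NumericVector spacing) {
  const double INF = std::numeric_limits<double>::infinity();
  int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  std::vector<double> sq(n);
  for (R_xlen_t i = 0; i < n; ++i) sq[i] = mask[i] ? 0.0 : INF;

  std::vector<double> f, d;

  // axis 1 (fastest index), step spacing[0]
  f.resize(n1);
  for (R_xlen_t c = 0; c < (R_xlen_t)n2 * n3; ++c) {
    R_xlen_t base = c * n1;
    for (int q = 0; q < n1; ++q) f[q] = sq[base + q];
    dt1d(f, spacing[0], d);
    for (int q = 0; q < n1; ++q) sq[base + q] = d[q];
  }
  // axis 2, step spacing[1]
  f.resize(n2);
  for (int k = 0; k < n3; ++k) {
    for (int i = 0; i < n1; ++i) {
      R_xlen_t base = (R_xlen_t)k * n1 * n2 + i;
      for (int q = 0; q < n2; ++q) f[q] = sq[base + (R_xlen_t)q * n1];
      dt1d(f, spacing[1], d);
      for (int q = 0; q < n2; ++q) sq[base + (R_xlen_t)q * n1] = d[q];
    }
  }
  // axis 3, step spacing[2]
  f.resize(n3);
  R_xlen_t stride = (R_xlen_t)n1 * n2;
  NumericVector out(n);
  for (R_xlen_t c = 0; c < stride; ++c) {
    for (int q = 0; q < n3; ++q) f[q] = sq[c + (R_xlen_t)q * stride];
    dt1d(f, spacing[2], d);
    for (int q = 0; q < n3; ++q)
      out[c + (R_xlen_t)q * stride] = std::sqrt(d[q]);
  }
  return out;
}
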