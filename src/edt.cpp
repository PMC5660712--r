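#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// 1D squared-distance transform (Felzenszwalb & Huttenlocher) with physical
// sample spacing w: input f at positions i*w, output d[i] = min_j f[j] + (i-j)^2 w^2.
static void dt1d(const std::vector<double> &f, std::vector<double> &d, double w) {
  const int n = f.size();
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  const double w2 = w * w;
  int k = -1;                      // infinite samples never form parabolas
  for (int q = 0; q < n; ++q) {
    if (f[q] == INF) continue;
    if (k < 0) {
      k = 0; v[0] = q; z[0] = -INF; z[1] = INF;
      continue;
    }
    double s;
    while (true) {
      const int p = v[k];
      s = ((f[q] + w2 * q * q) - (f[p] + w2 * p * p)) / (2.0 * w2 * (q - p));
      if (k > 0 && s <= z[k]) { --k; continue; }
      break;
    }
    ++k; v[k] = q; z[k] = s; z[k + 1] = INF;
  }
  if (k < 0) { for (int q = 0; q < n; ++q) d[q] = INF; return; }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    const double dq = w * (q - v[k]);
    d[q] = f[v[k]] + dq * dq;
  }
}

// Anisotropic Euclidean distance transform: distance (in the units of
// `spacing`) from each voxel center to the nearest voxel center where
// feature != 0.
// [[Rcpp::export]]
NumericVector cpp_edt(IntegerVector feature, IntegerVector dims, NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const double INF = std::numeric_limits<double>::infinity();
  NumericVector D(n);
  for (R_xlen_t i = 0; i < n; ++i) D[i] = feature[i] != 0 ? 0.0 : INF;
  const R_xlen_t sy = nx, sz = (R_xlen_t)nx * ny;
  std::vector<double> f, d;
  // x pass
  f.resize(nx); d.resize(nx);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      const R_xlen_t base = sy * y + sz * z;
      for (int x = 0; x < nx; ++x) f[x] = D[base + x];
      dt1d(f, d, spacing[0]);
      for (int x = 0; x < nx; ++x) D[base + x] = d[x];
    }
  // y pass
  f.resize(ny); d.resize(ny);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      const R_xlen_t base = x + sz * z;
      for (int y = 0; y < ny; ++y) f[y] = D[base + sy * y];
      dt1d(f, d, spacing[1]);
      for (int y = 0; y < ny; ++y) D[base + sy * y] = d[y];
    }
  // z pass
  f.resize(nz); d.resize(nz);
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      const R_xlen_t base = x + sy * y;
      for (int z = 0; z < nz; ++z) f[z] = D[base + sz * z];
      dt1d(f, d, spacing[2]);
      for (int z = 0; z < nz; ++z) D[base + sz * z] = d[z];
    }
  for (R_xlen_t i = 0; i < n; ++i) D[i] = std::sqrt(D[i]);
  return D;
}
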