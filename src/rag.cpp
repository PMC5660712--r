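#include <Rcpp.h>
#include <map>
#include <vector>
using namespace Rcpp;

static inline int bin_of(double v, int nbins) {
  int b = (int)(v * nbins);
  if (b < 0) b = 0;
  if (b >= nbins) b = nbins - 1;
  return b;
}

// Per-edge accumulated statistics for a region adjacency graph on a label
// volume (6-connectivity).  For every unordered pair of face-adjacent labels
// (a < b) we accumulate, over the two voxels of every shared face: contact
// area (face count) and, for the two value channels (assumed in [0,1]),
// power sums s^1..s^4 and histogram counts.
// Columns: a, b, area, v1: s1 s2 s3 s4 h1..h{nbins}, v2: likewise.
// [[Rcpp::export]]
NumericMatrix cpp_edge_stats(IntegerVector labels, IntegerVector dims,
                             NumericVector v1, NumericVector v2, int nbins) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t sy = nx, sz = (R_xlen_t)nx * ny;
  const int ncol = 3 + 2 * (4 + nbins);
  std::map<std::pair<int, int>, int> edge_id;
  std::vector<std::vector<double>> rows;
  const R_xlen_t strides[3] = {1, sy, sz};
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const R_xlen_t i = x + sy * y + sz * z;
        const int la = labels[i];
        const int lim[3] = {nx - 1 - x, ny - 1 - y, nz - 1 - z};
        for (int ax = 0; ax < 3; ++ax) {
          if (lim[ax] <= 0) continue;
          const R_xlen_t j = i + strides[ax];
          const int lb = labels[j];
          if (la == lb) continue;
          std::pair<int, int> key = la < lb ? std::make_pair(la, lb) : std::make_pair(lb, la);
          auto it = edge_id.find(key);
          int id;
          if (it == edge_id.end()) {
            id = rows.size();
            edge_id[key] = id;
            rows.push_back(std::vector<double>(ncol, 0.0));
            rows[id][0] = key.first; rows[id][1] = key.second;
          } else id = it->second;
          std::vector<double> &r = rows[id];
          r[2] += 1.0;
          const double vals1[2] = {v1[i], v1[j]};
          const double vals2[2] = {v2[i], v2[j]};
          for (int t = 0; t < 2; ++t) {
            double p = vals1[t];
            r[3] += p; r[4] += p * p; r[5] += p * p * p; r[6] += p * p * p * p;
            r[7 + bin_of(p, nbins)] += 1.0;
            p = vals2[t];
            int off = 3 + 4 + nbins;
            r[off] += p; r[off + 1] += p * p; r[off + 2] += p * p * p; r[off + 3] += p * p * p * p;
            r[off + 4 + bin_of(p, nbins)] += 1.0;
          }
        }
      }
  NumericMatrix out(rows.size(), ncol);
  for (size_t i = 0; i < rows.size(); ++i)
    for (int j = 0; j < ncol; ++j) out(i, j) = rows[i][j];
  return out;
}

// Per-label body statistics: voxel count plus power sums and histograms of
// the two value channels.  Labels must be 1..nlabels.
// Columns: count, v1: s1 s2 s3 s4 h1..h{nbins}, v2: likewise.
// [[Rcpp::export]]
NumericMatrix cpp_body_stats(IntegerVector labels, NumericVector v1,
                             NumericVector v2, int nlabels, int nbins) {
  const int ncol = 1 + 2 * (4 + nbins);
  NumericMatrix out(nlabels, ncol);
  const R_xlen_t n = labels.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    const int l = labels[i] - 1;
    if (l < 0 || l >= nlabels) continue;
    out(l, 0) += 1.0;
    double p = v1[i];
    out(l, 1) += p; out(l, 2) += p * p; out(l, 3) += p * p * p; out(l, 4) += p * p * p * p;
    out(l, 5 + bin_of(p, nbins)) += 1.0;
    p = v2[i];
    const int off = 1 + 4 + nbins;
    out(l, off) += p; out(l, off + 1) += p * p; out(l, off + 2) += p * p * p; out(l, off + 3) += p * p * p * p;
    out(l, off + 4 + bin_of(p, nbins)) += 1.0;
  }
  return out;
}
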