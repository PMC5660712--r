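#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

static inline void decode(R_xlen_t i, int nx, int ny, int &x, int &y, int &z) {
  x = i % nx; y = (i / nx) % ny; z = i / ((R_xlen_t)nx * ny);
}

// Grayscale reconstruction by dilation of `marker` under `mask`
// (marker <= mask pointwise), hybrid raster-scan + FIFO algorithm,
// 6-connectivity.
// [[Rcpp::export]]
NumericVector cpp_reconstruct_dilation(NumericVector marker, NumericVector mask,
                                       IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector J = clone(marker);
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  // forward scan (neighbors already visited: -x, -y, -z)
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const R_xlen_t i = x + sy * y + sz * z;
        double v = J[i];
        if (x > 0 && J[i - sx] > v) v = J[i - sx];
        if (y > 0 && J[i - sy] > v) v = J[i - sy];
        if (z > 0 && J[i - sz] > v) v = J[i - sz];
        J[i] = std::min(v, mask[i]);
      }
  // backward scan + queue seeding
  std::queue<R_xlen_t> q;
  for (int z = nz - 1; z >= 0; --z)
    for (int y = ny - 1; y >= 0; --y)
      for (int x = nx - 1; x >= 0; --x) {
        const R_xlen_t i = x + sy * y + sz * z;
        double v = J[i];
        if (x < nx - 1 && J[i + sx] > v) v = J[i + sx];
        if (y < ny - 1 && J[i + sy] > v) v = J[i + sy];
        if (z < nz - 1 && J[i + sz] > v) v = J[i + sz];
        J[i] = std::min(v, mask[i]);
        bool push = false;
        if (x < nx - 1 && J[i + sx] < J[i] && J[i + sx] < mask[i + sx]) push = true;
        if (y < ny - 1 && J[i + sy] < J[i] && J[i + sy] < mask[i + sy]) push = true;
        if (z < nz - 1 && J[i + sz] < J[i] && J[i + sz] < mask[i + sz]) push = true;
        if (push) q.push(i);
      }
  const int dx[6] = {-1, 1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, -1, 1, 0, 0};
  const int dz[6] = {0, 0, 0, 0, -1, 1};
  while (!q.empty()) {
    const R_xlen_t i = q.front(); q.pop();
    int x, y, z; decode(i, nx, ny, x, y, z);
    for (int k = 0; k < 6; ++k) {
      const int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
      const R_xlen_t j = xx + sy * yy + sz * zz;
      if (J[j] < J[i] && mask[j] != J[j]) {
        J[j] = std::min(J[i], mask[j]);
        q.push(j);
      }
    }
  }
  return J;
}

// Regional minima (6-connectivity): connected equal-value plateaus with no
// strictly lower neighbor.  Minima labeled 1..k in lexicographic order of
// their first voxel; non-minima are 0.
// [[Rcpp::export]]
IntegerVector cpp_regional_minima(NumericVector xv, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<char> visited(n, 0);
  const int dx[6] = {-1, 1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, -1, 1, 0, 0};
  const int dz[6] = {0, 0, 0, 0, -1, 1};
  int next = 0;
  std::vector<R_xlen_t> plateau;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (visited[s]) continue;
    const double v = xv[s];
    plateau.clear();
    bool is_min = true;
    std::queue<R_xlen_t> q;
    q.push(s); visited[s] = 1;
    while (!q.empty()) {
      const R_xlen_t i = q.front(); q.pop();
      plateau.push_back(i);
      int x, y, z; decode(i, nx, ny, x, y, z);
      for (int k = 0; k < 6; ++k) {
        const int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
        const R_xlen_t j = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
        if (xv[j] < v) is_min = false;
        else if (xv[j] == v && !visited[j]) { visited[j] = 1; q.push(j); }
      }
    }
    if (is_min) {
      ++next;
      for (R_xlen_t i : plateau) lab[i] = next;
    }
  }
  return lab;
}

struct WsEntry {
  double val;
  long long order;
  R_xlen_t idx;
  int label;
};
struct WsCmp {
  bool operator()(const WsEntry &a, const WsEntry &b) const {
    if (a.val != b.val) return a.val > b.val;   // min-heap on value
    return a.order > b.order;                    // FIFO tie-break
  }
};

// Seeded watershed (Meyer flooding, 6-connectivity, no watershed lines).
// Seeds are enqueued in lexicographic voxel order; ties broken by insertion
// order so the result is deterministic.
// [[Rcpp::export]]
IntegerVector cpp_watershed(NumericVector xv, IntegerVector seeds, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::priority_queue<WsEntry, std::vector<WsEntry>, WsCmp> pq;
  long long order = 0;
  for (R_xlen_t i = 0; i < n; ++i)
    if (seeds[i] != 0) pq.push({xv[i], order++, i, seeds[i]});
  const int dx[6] = {-1, 1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, -1, 1, 0, 0};
  const int dz[6] = {0, 0, 0, 0, -1, 1};
  while (!pq.empty()) {
    const WsEntry e = pq.top(); pq.pop();
    if (lab[e.idx] != 0) continue;
    lab[e.idx] = e.label;
    int x, y, z; decode(e.idx, nx, ny, x, y, z);
    for (int k = 0; k < 6; ++k) {
      const int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
      const R_xlen_t j = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
      if (lab[j] == 0) pq.push({xv[j], order++, j, e.label});
    }
  }
  return lab;
}
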