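#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

// labels are stored in R column-major order: idx = x + nx*(y + ny*z), 0-based here

// [[Rcpp::export]]
IntegerVector cpp_stamp_spheres(IntegerVector dims, NumericMatrix centers,
                                NumericVector radii, IntegerVector labels) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerVector vol(nx * ny * nz, 0);
  const int n = centers.nrow();
  for (int p = 0; p < n; ++p) {
    const double cx = centers(p, 0), cy = centers(p, 1), cz = centers(p, 2);
    const double r = radii[p], r2 = r * r;
    const int lab = labels[p];
    const int x0 = std::max(0, (int)std::floor(cx - r)), x1 = std::min(nx - 1, (int)std::ceil(cx + r));
    const int y0 = std::max(0, (int)std::floor(cy - r)), y1 = std::min(ny - 1, (int)std::ceil(cy + r));
    const int z0 = std::max(0, (int)std::floor(cz - r)), z1 = std::min(nz - 1, (int)std::ceil(cz + r));
    for (int z = z0; z <= z1; ++z) {
      const double dz = z - cz;
      for (int y = y0; y <= y1; ++y) {
        const double dy = y - cy;
        const double rem = r2 - dz * dz - dy * dy;
        if (rem < 0) continue;
        for (int x = x0; x <= x1; ++x) {
          const double dx = x - cx;
          if (dx * dx <= rem) {
            const R_xlen_t idx = (R_xlen_t)x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
            if (vol[idx] == 0) vol[idx] = lab;
          }
        }
      }
    }
  }
  return vol;
}

// Multi-source BFS (6-connectivity) assigning unlabeled voxels to the nearest
// labeled structure in the BFS metric; deterministic: seeds enqueued in
// lexicographic order and ties resolved first-come-first-served.
// [[Rcpp::export]]
IntegerVector cpp_flood_nearest(IntegerVector labels, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector out = clone(labels);
  std::queue<R_xlen_t> q;
  for (R_xlen_t i = 0; i < n; ++i) if (out[i] != 0) q.push(i);
  const int dx[6] = {-1, 1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, -1, 1, 0, 0};
  const int dz[6] = {0, 0, 0, 0, -1, 1};
  while (!q.empty()) {
    const R_xlen_t i = q.front(); q.pop();
    const int x = i % nx, y = (i / nx) % ny, z = i / ((R_xlen_t)nx * ny);
    for (int k = 0; k < 6; ++k) {
      const int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
      const R_xlen_t j = (R_xlen_t)xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
      if (out[j] == 0) { out[j] = out[i]; q.push(j); }
    }
  }
  return out;
}

// Membrane mask under 6-connectivity: voxel is boundary iff a face neighbor
// carries a different label; out-of-bounds neighbors never create boundary.
// [[Rcpp::export]]
LogicalVector cpp_boundary6(IntegerVector labels, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector out(n, false);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const R_xlen_t i = (R_xlen_t)x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
        const int lab = labels[i];
        bool b = false;
        if (x > 0      && labels[i - 1] != lab) b = true;
        else if (x < nx - 1 && labels[i + 1] != lab) b = true;
        else if (y > 0      && labels[i - nx] != lab) b = true;
        else if (y < ny - 1 && labels[i + nx] != lab) b = true;
        else if (z > 0      && labels[i - (R_xlen_t)nx * ny] != lab) b = true;
        else if (z < nz - 1 && labels[i + (R_xlen_t)nx * ny] != lab) b = true;
        out[i] = b;
      }
  return out;
}

// Deposit Gaussian-spread point masses onto a voxel grid.  Per-axis weights
// are normalized by their discrete sums, so each point's amplitude is
// conserved exactly regardless of the truncation radius (3 sigma per axis).
// Points are given in nm relative to the volume origin; voxel centers sit at
// (i + 0.5) * voxel_size.
// [[Rcpp::export]]
NumericVector cpp_rasterize_points(IntegerVector dims, double voxel_size,
                                   NumericMatrix pts, NumericVector amp,
                                   NumericVector sigma) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector vol((R_xlen_t)nx * ny * nz, 0.0);
  const int n = pts.nrow();
  std::vector<double> wx, wy, wz;
  for (int p = 0; p < n; ++p) {
    const double s = sigma[p];
    // continuous voxel coordinate of the point (voxel center i at coord i)
    const double cx = pts(p, 0) / voxel_size - 0.5;
    const double cy = pts(p, 1) / voxel_size - 0.5;
    const double cz = pts(p, 2) / voxel_size - 0.5;
    if (s <= 0) {
      const int x = (int)std::lround(cx), y = (int)std::lround(cy), z = (int)std::lround(cz);
      if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz) continue;
      vol[(R_xlen_t)x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)] += amp[p];
      continue;
    }
    const double sv = s / voxel_size;           // sigma in voxels
    const int r = std::max(1, (int)std::ceil(3.0 * sv));
    const int x0 = std::max(0, (int)std::floor(cx) - r), x1 = std::min(nx - 1, (int)std::floor(cx) + r + 1);
    const int y0 = std::max(0, (int)std::floor(cy) - r), y1 = std::min(ny - 1, (int)std::floor(cy) + r + 1);
    const int z0 = std::max(0, (int)std::floor(cz) - r), z1 = std::min(nz - 1, (int)std::floor(cz) + r + 1);
    if (x1 < x0 || y1 < y0 || z1 < z0) continue;
    wx.assign(x1 - x0 + 1, 0.0); wy.assign(y1 - y0 + 1, 0.0); wz.assign(z1 - z0 + 1, 0.0);
    double sx = 0, sy = 0, sz = 0;
    const double inv2 = 1.0 / (2.0 * sv * sv);
    for (int x = x0; x <= x1; ++x) { const double d = x - cx; wx[x - x0] = std::exp(-d * d * inv2); sx += wx[x - x0]; }
    for (int y = y0; y <= y1; ++y) { const double d = y - cy; wy[y - y0] = std::exp(-d * d * inv2); sy += wy[y - y0]; }
    for (int z = z0; z <= z1; ++z) { const double d = z - cz; wz[z - z0] = std::exp(-d * d * inv2); sz += wz[z - z0]; }
    if (sx <= 0 || sy <= 0 || sz <= 0) continue;
    const double a = amp[p] / (sx * sy * sz);
    double *vp = REAL(vol);
    const double *wxp = wx.data();
    const int nxr = x1 - x0 + 1;
    for (int z = z0; z <= z1; ++z) {
      const double az = a * wz[z - z0];
      for (int y = y0; y <= y1; ++y) {
        const double ay = az * wy[y - y0];
        double *row = vp + x0 + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
        for (int x = 0; x < nxr; ++x) row[x] += ay * wxp[x];
      }
    }
  }
  return vol;
}

// 3D median filter with clamped (replicate) borders.
// [[Rcpp::export]]
NumericVector cpp_median3d(NumericVector x, IntegerVector dims, IntegerVector size) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int rx = size[0] / 2, ry = size[1] / 2, rz = size[2] / 2;
  NumericVector out((R_xlen_t)nx * ny * nz);
  std::vector<double> buf;
  buf.reserve((2 * rx + 1) * (2 * ry + 1) * (2 * rz + 1));
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int xx = 0; xx < nx; ++xx) {
        buf.clear();
        for (int dz = -rz; dz <= rz; ++dz) {
          int zz = std::min(nz - 1, std::max(0, z + dz));
          for (int dy = -ry; dy <= ry; ++dy) {
            int yy = std::min(ny - 1, std::max(0, y + dy));
            for (int dx = -rx; dx <= rx; ++dx) {
              int xv = std::min(nx - 1, std::max(0, xx + dx));
              buf.push_back(x[(R_xlen_t)xv + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz)]);
            }
          }
        }
        size_t mid = buf.size() / 2;
        std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
        double med = buf[mid];
        if (buf.size() % 2 == 0) {
          std::nth_element(buf.begin(), buf.begin() + mid - 1, buf.begin() + mid);
          med = 0.5 * (med + buf[mid - 1]);
        }
        out[(R_xlen_t)xx + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)] = med;
      }
  return out;
}
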