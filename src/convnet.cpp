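#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Tensors use R column-major layout with an optional trailing batch axis:
//   activations x: dim (nx, ny, nz, c, nb)   (nb = 1 for dense inference)
//   weights    w: dim (kx, ky, kz, ci, co)
// Valid (un-padded) cross-correlation with per-axis dilation.

// [[Rcpp::export]]
NumericVector cpp_conv3d_fwd(NumericVector x, IntegerVector xd,
                             NumericVector w, IntegerVector wd,
                             NumericVector bias, IntegerVector dil) {
  const int nx = xd[0], ny = xd[1], nz = xd[2], ci = xd[3];
  const int nb = xd.size() > 4 ? xd[4] : 1;
  const int kx = wd[0], ky = wd[1], kz = wd[2], co = wd[4];
  const int dx = dil[0], dy = dil[1], dz = dil[2];
  const int ox = nx - (kx - 1) * dx, oy = ny - (ky - 1) * dy, oz = nz - (kz - 1) * dz;
  if (ox <= 0 || oy <= 0 || oz <= 0) stop("input smaller than (dilated) kernel");
  NumericVector y((R_xlen_t)ox * oy * oz * co * nb);
  y.attr("dim") = xd.size() > 4 ? IntegerVector::create(ox, oy, oz, co, nb)
                                : IntegerVector::create(ox, oy, oz, co);
  const R_xlen_t xsy = nx, xsz = (R_xlen_t)nx * ny, xsc = (R_xlen_t)nx * ny * nz,
                 xsb = xsc * ci;
  const R_xlen_t ysy = ox, ysz = (R_xlen_t)ox * oy, ysc = (R_xlen_t)ox * oy * oz,
                 ysb = ysc * co;
  const R_xlen_t wsy = kx, wsz = (R_xlen_t)kx * ky, wsi = (R_xlen_t)kx * ky * kz,
                 wso = wsi * ci;
  const double *X = REAL(x), *W = REAL(w), *B = REAL(bias);
  double *Y = REAL(y);
  // accumulate one scalar weight times a shifted input plane at a time, so
  // the inner loop is contiguous in both input and output
  for (int b = 0; b < nb; ++b)
    for (int c = 0; c < co; ++c) {
      double *yp = Y + ysb * b + ysc * c;
      const double b0 = B[c];
      for (R_xlen_t i = 0; i < ysc; ++i) yp[i] = b0;
      for (int ic = 0; ic < ci; ++ic) {
        const double *xp = X + xsb * b + xsc * ic;
        const double *wp = W + wso * c + wsi * ic;
        for (int az = 0; az < kz; ++az)
          for (int ay = 0; ay < ky; ++ay)
            for (int ax = 0; ax < kx; ++ax) {
              const double wv = wp[ax + wsy * ay + wsz * az];
              if (wv == 0) continue;
              const double *xs = xp + ax * dx + xsy * (R_xlen_t)(ay * dy) +
                                 xsz * (R_xlen_t)(az * dz);
              for (int z = 0; z < oz; ++z)
                for (int yy = 0; yy < oy; ++yy) {
                  const double *xr = xs + xsy * yy + xsz * z;
                  double *yr = yp + ysy * yy + ysz * z;
                  for (int xx = 0; xx < ox; ++xx) yr[xx] += wv * xr[xx];
                }
            }
      }
    }
  return y;
}

// Gradients w.r.t. input, weights and bias; weight/bias gradients are summed
// over the batch.
// [[Rcpp::export]]
List cpp_conv3d_bwd(NumericVector x, IntegerVector xd,
                    NumericVector w, IntegerVector wd,
                    NumericVector gy, IntegerVector dil) {
  const int nx = xd[0], ny = xd[1], nz = xd[2], ci = xd[3];
  const int nb = xd.size() > 4 ? xd[4] : 1;
  const int kx = wd[0], ky = wd[1], kz = wd[2], co = wd[4];
  const int dx = dil[0], dy = dil[1], dz = dil[2];
  const int ox = nx - (kx - 1) * dx, oy = ny - (ky - 1) * dy, oz = nz - (kz - 1) * dz;
  NumericVector gx((R_xlen_t)nx * ny * nz * ci * nb);
  gx.attr("dim") = xd;
  NumericVector gw(w.size());
  gw.attr("dim") = wd;
  NumericVector gb(co);
  const R_xlen_t xsy = nx, xsz = (R_xlen_t)nx * ny, xsc = (R_xlen_t)nx * ny * nz,
                 xsb = xsc * ci;
  const R_xlen_t ysy = ox, ysz = (R_xlen_t)ox * oy, ysc = (R_xlen_t)ox * oy * oz,
                 ysb = ysc * co;
  const R_xlen_t wsy = kx, wsz = (R_xlen_t)kx * ky, wsi = (R_xlen_t)kx * ky * kz,
                 wso = wsi * ci;
  const double *X = REAL(x), *W = REAL(w), *GY = REAL(gy);
  double *GX = REAL(gx), *GW = REAL(gw), *GB = REAL(gb);
  for (int b = 0; b < nb; ++b)
    for (int c = 0; c < co; ++c) {
      const double *gyp = GY + ysb * b + ysc * c;
      for (R_xlen_t i = 0; i < ysc; ++i) GB[c] += gyp[i];
      for (int ic = 0; ic < ci; ++ic) {
        const double *xp = X + xsb * b + xsc * ic;
        double *gxp = GX + xsb * b + xsc * ic;
        const double *wp = W + wso * c + wsi * ic;
        double *gwp = GW + wso * c + wsi * ic;
        for (int az = 0; az < kz; ++az)
          for (int ay = 0; ay < ky; ++ay)
            for (int ax = 0; ax < kx; ++ax) {
              const R_xlen_t shift = ax * (R_xlen_t)dx + xsy * (R_xlen_t)(ay * dy) +
                                     xsz * (R_xlen_t)(az * dz);
              const double wv = wp[ax + wsy * ay + wsz * az];
              double gwacc = 0;
              for (int z = 0; z < oz; ++z)
                for (int yy = 0; yy < oy; ++yy) {
                  const double *gr = gyp + ysy * yy + ysz * z;
                  const double *xr = xp + shift + xsy * yy + xsz * z;
                  double *gxr = gxp + shift + xsy * yy + xsz * z;
                  for (int xx = 0; xx < ox; ++xx) {
                    gwacc += gr[xx] * xr[xx];
                    gxr[xx] += gr[xx] * wv;
                  }
                }
              gwp[ax + wsy * ay + wsz * az] += gwacc;
            }
      }
    }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Max pooling per channel (and batch) with window `size`, window-element
// spacing `dil` and output stride `stride`.  Training uses stride == size
// (dil 1); dense inference uses stride 1 with accumulated dilation.
// Returns pooled tensor and 0-based flat argmax indices into x.
// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector x, IntegerVector xd,
                     IntegerVector size, IntegerVector stride, IntegerVector dil) {
  const int nx = xd[0], ny = xd[1], nz = xd[2], nc = xd[3];
  const int nb = xd.size() > 4 ? xd[4] : 1;
  const int px = size[0], py = size[1], pz = size[2];
  const int sx = stride[0], sy = stride[1], sz = stride[2];
  const int dx = dil[0], dy = dil[1], dz = dil[2];
  const int ex = (px - 1) * dx, ey = (py - 1) * dy, ez = (pz - 1) * dz;
  const int ox = (nx - 1 - ex) / sx + 1, oy = (ny - 1 - ey) / sy + 1,
            oz = (nz - 1 - ez) / sz + 1;
  if (ox <= 0 || oy <= 0 || oz <= 0) stop("input smaller than pooling window");
  NumericVector y((R_xlen_t)ox * oy * oz * nc * nb);
  y.attr("dim") = xd.size() > 4 ? IntegerVector::create(ox, oy, oz, nc, nb)
                                : IntegerVector::create(ox, oy, oz, nc);
  NumericVector am(y.size());           // double to allow >2^31 in principle
  const R_xlen_t Xsy = nx, Xsz = (R_xlen_t)nx * ny, Xsc = (R_xlen_t)nx * ny * nz,
                 Xsb = Xsc * nc;
  const double *X = REAL(x);
  double *Y = REAL(y), *AM = REAL(am);
  R_xlen_t oi = 0;
  for (int b = 0; b < nb; ++b)
    for (int c = 0; c < nc; ++c)
      for (int z = 0; z < oz; ++z)
        for (int yy = 0; yy < oy; ++yy)
          for (int xx = 0; xx < ox; ++xx, ++oi) {
            const int bx = xx * sx, by = yy * sy, bz = z * sz;
            double best = R_NegInf;
            R_xlen_t bidx = -1;
            for (int az = 0; az < pz; ++az)
              for (int ay = 0; ay < py; ++ay)
                for (int ax = 0; ax < px; ++ax) {
                  const R_xlen_t i = (bx + ax * dx) + Xsy * (by + ay * dy) +
                                     Xsz * (bz + az * dz) + Xsc * c + Xsb * b;
                  if (X[i] > best) { best = X[i]; bidx = i; }
                }
            Y[oi] = best;
            AM[oi] = (double)bidx;
          }
  return List::create(_["y"] = y, _["argmax"] = am);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(IntegerVector xd, NumericVector argmax, NumericVector gy) {
  R_xlen_t n = 1;
  for (int i = 0; i < xd.size(); ++i) n *= xd[i];
  NumericVector gx(n);
  gx.attr("dim") = xd;
  double *GX = REAL(gx);
  const double *AM = REAL(argmax), *GY = REAL(gy);
  for (R_xlen_t i = 0; i < gy.size(); ++i) GX[(R_xlen_t)AM[i]] += GY[i];
  return gx;
}
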