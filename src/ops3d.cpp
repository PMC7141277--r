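#include <Rcpp.h>
using namespace Rcpp;

// Volumetric feature maps are stored as (nvox x channels) matrices whose row
// index runs x-fastest over a (d1, d2, d3) grid (R array order). Convolutions
// use odd kernels with zero padding of (k-1)/2, so spatial size is preserved;
// the matrix-multiply itself is done in R via BLAS on the im2col output.

// im2col: column block o*C + c holds channel c shifted by kernel offset o.
// [[Rcpp::export]]
NumericMatrix cpp_im2col(const NumericMatrix& x, int d1, int d2, int d3, int k) {
  const int nvox = d1 * d2 * d3, C = x.ncol(), p = (k - 1) / 2;
  if (x.nrow() != nvox) stop("im2col: row count does not match grid");
  NumericMatrix col(nvox, k * k * k * C);
  int o = 0;
  for (int oz = -p; oz <= p; ++oz)
    for (int oy = -p; oy <= p; ++oy)
      for (int ox = -p; ox <= p; ++ox, ++o) {
        for (int c = 0; c < C; ++c) {
          double* dst = &col(0, o * C + c);
          const double* src = &x(0, c);
          for (int z = 0; z < d3; ++z) {
            const int zz = z + oz;
            if (zz < 0 || zz >= d3) continue;
            for (int y = 0; y < d2; ++y) {
              const int yy = y + oy;
              if (yy < 0 || yy >= d2) continue;
              const int base = (z * d2 + y) * d1;
              const int sbase = (zz * d2 + yy) * d1 + ox;
              const int x0 = std::max(0, -ox), x1 = std::min(d1, d1 - ox);
              for (int xi = x0; xi < x1; ++xi) dst[base + xi] = src[sbase + xi];
            }
          }
        }
      }
  return col;
}

// col2im: adjoint of im2col (scatter-add), used for the input gradient.
// [[Rcpp::export]]
NumericMatrix cpp_col2im(const NumericMatrix& dcol, int d1, int d2, int d3,
                         int k, int C) {
  const int nvox = d1 * d2 * d3, p = (k - 1) / 2;
  if (dcol.nrow() != nvox || dcol.ncol() != k * k * k * C)
    stop("col2im: dimension mismatch");
  NumericMatrix dx(nvox, C);
  int o = 0;
  for (int oz = -p; oz <= p; ++oz)
    for (int oy = -p; oy <= p; ++oy)
      for (int ox = -p; ox <= p; ++ox, ++o) {
        for (int c = 0; c < C; ++c) {
          const double* src = &dcol(0, o * C + c);
          double* dst = &dx(0, c);
          for (int z = 0; z < d3; ++z) {
            const int zz = z - oz;
            if (zz < 0 || zz >= d3) continue;
            for (int y = 0; y < d2; ++y) {
              const int yy = y - oy;
              if (yy < 0 || yy >= d2) continue;
              const int base = (z * d2 + y) * d1;
              const int sbase = (zz * d2 + yy) * d1 - ox;
              const int x0 = std::max(0, ox), x1 = std::min(d1, d1 + ox);
              for (int xi = x0; xi < x1; ++xi) dst[base + xi] += src[sbase + xi];
            }
          }
        }
      }
  return dx;
}

// 2x2x2 max pooling; dims must be even. Returns pooled values and the
// 0-based argmax row index in the input (per channel) for the backward pass.
// [[Rcpp::export]]
List cpp_maxpool(const NumericMatrix& x, int d1, int d2, int d3) {
  const int C = x.ncol(), e1 = d1 / 2, e2 = d2 / 2, e3 = d3 / 2;
  if (d1 % 2 || d2 % 2 || d3 % 2) stop("maxpool: dims must be even");
  if (x.nrow() != d1 * d2 * d3) stop("maxpool: row count does not match grid");
  NumericMatrix y(e1 * e2 * e3, C);
  IntegerMatrix idx(e1 * e2 * e3, C);
  for (int c = 0; c < C; ++c) {
    const double* src = &x(0, c);
    for (int z = 0; z < e3; ++z)
      for (int yy = 0; yy < e2; ++yy)
        for (int xx = 0; xx < e1; ++xx) {
          const int out = (z * e2 + yy) * e1 + xx;
          double best = R_NegInf;
          int bi = -1;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx) {
                const int v =
                    ((2 * z + dz) * d2 + (2 * yy + dy)) * d1 + (2 * xx + dx);
                if (src[v] > best) { best = src[v]; bi = v; }
              }
          y(out, c) = best;
          idx(out, c) = bi;
        }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericMatrix cpp_maxpool_bw(const NumericMatrix& dy, const IntegerMatrix& idx,
                             int nvox_in) {
  const int C = dy.ncol();
  NumericMatrix dx(nvox_in, C);
  for (int c = 0; c < C; ++c)
    for (int i = 0; i < dy.nrow(); ++i) dx(idx(i, c), c) += dy(i, c);
  return dx;
}

// Nearest-neighbour 2x upsampling; (d1, d2, d3) are the *input* dims.
// [[Rcpp::export]]
NumericMatrix cpp_upsample(const NumericMatrix& x, int d1, int d2, int d3) {
  const int C = x.ncol(), e1 = 2 * d1, e2 = 2 * d2, e3 = 2 * d3;
  if (x.nrow() != d1 * d2 * d3) stop("upsample: row count does not match grid");
  NumericMatrix y(e1 * e2 * e3, C);
  for (int c = 0; c < C; ++c) {
    const double* src = &x(0, c);
    double* dst = &y(0, c);
    for (int z = 0; z < e3; ++z)
      for (int yy = 0; yy < e2; ++yy) {
        const int sb = ((z / 2) * d2 + (yy / 2)) * d1;
        const int db = (z * e2 + yy) * e1;
        for (int xx = 0; xx < e1; ++xx) dst[db + xx] = src[sb + xx / 2];
      }
  }
  return y;
}

// [[Rcpp::export]]
NumericMatrix cpp_upsample_bw(const NumericMatrix& dy, int d1, int d2, int d3) {
  const int C = dy.ncol(), e1 = 2 * d1, e2 = 2 * d2, e3 = 2 * d3;
  if (dy.nrow() != e1 * e2 * e3) stop("upsample_bw: row count mismatch");
  NumericMatrix dx(d1 * d2 * d3, C);
  for (int c = 0; c < C; ++c) {
    const double* src = &dy(0, c);
    double* dst = &dx(0, c);
    for (int z = 0; z < e3; ++z)
      for (int yy = 0; yy < e2; ++yy) {
        const int db = ((z / 2) * d2 + (yy / 2)) * d1;
        const int sb = (z * e2 + yy) * e1;
        for (int xx = 0; xx < e1; ++xx) dst[db + xx / 2] += src[sb + xx];
      }
  }
  return dx;
}
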