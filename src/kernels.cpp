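#include <Rcpp.h>
using namespace Rcpp;

// Volumetric im2col / col2im, max-pooling, and LeakyReLU kernels.
//
// Activation blocks are R column-major 5-D arrays (d1, d2, d3, B, C):
// three spatial axes, batch, channels. Patch matrices have one row per
// output voxel, rows ordered spatial-fastest then batch; one column per
// patch entry, columns ordered kx, ky, kz, channel. With this layout the
// GEMM output (nsp*B x filters) is already the next activation block, so
// no permutation copies are needed. The convolution itself is a single
// BLAS GEMM on the R side; these kernels only gather/scatter.

static inline void out_dims(const IntegerVector& dims, int k, int stride,
                            int pad_lo, int pad_hi, int* o) {
  for (int a = 0; a < 3; ++a)
    o[a] = (dims[a] + pad_lo + pad_hi - k) / stride + 1;
}

// [[Rcpp::export]]
NumericMatrix im2col3(NumericVector x, IntegerVector dims, int k, int stride,
                      int pad_lo, int pad_hi) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2], B = dims[3],
            C = dims[4];
  int o[3];
  out_dims(dims, k, stride, pad_lo, pad_hi, o);
  const int o1 = o[0], o2 = o[1], o3 = o[2];
  const R_xlen_t nsp = (R_xlen_t)o1 * o2 * o3;
  const R_xlen_t nrow = nsp * B;
  const int ncol = k * k * k * C;
  NumericMatrix cols(nrow, ncol);
  const double* px = x.begin();
  double* pc = cols.begin();
  const R_xlen_t vox = (R_xlen_t)d1 * d2 * d3;  // voxels per (sample, channel)

  for (int c = 0; c < C; ++c) {
    for (int kz = 0; kz < k; ++kz) {
      for (int ky = 0; ky < k; ++ky) {
        for (int kx = 0; kx < k; ++kx) {
          const int q = kx + k * (ky + k * (kz + k * c));
          double* col = pc + (R_xlen_t)q * nrow;
          for (int b = 0; b < B; ++b) {
            const double* xb = px + ((R_xlen_t)c * B + b) * vox;
            double* rowp = col + (R_xlen_t)b * nsp;
            for (int oz = 0; oz < o3; ++oz) {
              const int iz = oz * stride - pad_lo + kz;
              const bool zok = iz >= 0 && iz < d3;
              for (int oy = 0; oy < o2; ++oy) {
                const int iy = oy * stride - pad_lo + ky;
                const bool yok = iy >= 0 && iy < d2;
                const R_xlen_t base =
                    zok && yok ? (R_xlen_t)d1 * (iy + (R_xlen_t)d2 * iz) : 0;
                for (int ox = 0; ox < o1; ++ox) {
                  const int ix = ox * stride - pad_lo + kx;
                  double v = 0.0;
                  if (zok && yok && ix >= 0 && ix < d1) v = xb[base + ix];
                  *rowp++ = v;
                }
              }
            }
          }
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export]]
NumericVector col2im3(NumericMatrix cols, IntegerVector dims, int k,
                      int stride, int pad_lo, int pad_hi) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2], B = dims[3],
            C = dims[4];
  int o[3];
  out_dims(dims, k, stride, pad_lo, pad_hi, o);
  const int o1 = o[0], o2 = o[1], o3 = o[2];
  const R_xlen_t nsp = (R_xlen_t)o1 * o2 * o3;
  const R_xlen_t nrow = nsp * B;
  NumericVector dx((R_xlen_t)d1 * d2 * d3 * B * C);
  const double* pc = cols.begin();
  double* px = dx.begin();
  const R_xlen_t vox = (R_xlen_t)d1 * d2 * d3;

  for (int c = 0; c < C; ++c) {
    for (int kz = 0; kz < k; ++kz) {
      for (int ky = 0; ky < k; ++ky) {
        for (int kx = 0; kx < k; ++kx) {
          const int q = kx + k * (ky + k * (kz + k * c));
          const double* col = pc + (R_xlen_t)q * nrow;
          for (int b = 0; b < B; ++b) {
            double* xb = px + ((R_xlen_t)c * B + b) * vox;
            const double* rowp = col + (R_xlen_t)b * nsp;
            for (int oz = 0; oz < o3; ++oz) {
              const int iz = oz * stride - pad_lo + kz;
              if (iz < 0 || iz >= d3) { rowp += (R_xlen_t)o1 * o2; continue; }
              for (int oy = 0; oy < o2; ++oy) {
                const int iy = oy * stride - pad_lo + ky;
                if (iy < 0 || iy >= d2) { rowp += o1; continue; }
                const R_xlen_t base = (R_xlen_t)d1 * (iy + (R_xlen_t)d2 * iz);
                for (int ox = 0; ox < o1; ++ox) {
                  const int ix = ox * stride - pad_lo + kx;
                  if (ix >= 0 && ix < d1) xb[base + ix] += *rowp;
                  ++rowp;
                }
              }
            }
          }
        }
      }
    }
  }
  return dx;
}

// Max-pooling forward: returns pooled values (layout (o1,o2,o3,B,C)) plus
// the 0-based linear index of the argmax within the input block (-1 for
// all-padded windows, which cannot occur for the supported geometries).
// [[Rcpp::export]]
List maxpool3_fwd(NumericVector x, IntegerVector dims, int k, int stride,
                  int pad_lo, int pad_hi) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2], B = dims[3],
            C = dims[4];
  int o[3];
  out_dims(dims, k, stride, pad_lo, pad_hi, o);
  const int o1 = o[0], o2 = o[1], o3 = o[2];
  const R_xlen_t nout = (R_xlen_t)o1 * o2 * o3 * B * C;
  NumericVector out(nout);
  IntegerVector which(nout);
  const double* px = x.begin();
  const R_xlen_t vox = (R_xlen_t)d1 * d2 * d3;
  R_xlen_t w = 0;

  for (int c = 0; c < C; ++c) {
    for (int b = 0; b < B; ++b) {
      const R_xlen_t off = ((R_xlen_t)c * B + b) * vox;
      const double* xb = px + off;
      for (int oz = 0; oz < o3; ++oz) {
        const int z0 = oz * stride - pad_lo;
        for (int oy = 0; oy < o2; ++oy) {
          const int y0 = oy * stride - pad_lo;
          for (int ox = 0; ox < o1; ++ox) {
            const int x0 = ox * stride - pad_lo;
            double best = R_NegInf;
            R_xlen_t arg = -1;
            for (int kz = 0; kz < k; ++kz) {
              const int iz = z0 + kz;
              if (iz < 0 || iz >= d3) continue;
              for (int ky = 0; ky < k; ++ky) {
                const int iy = y0 + ky;
                if (iy < 0 || iy >= d2) continue;
                const R_xlen_t base = (R_xlen_t)d1 * (iy + (R_xlen_t)d2 * iz);
                for (int kx = 0; kx < k; ++kx) {
                  const int ix = x0 + kx;
                  if (ix < 0 || ix >= d1) continue;
                  const double v = xb[base + ix];
                  if (v > best) { best = v; arg = off + base + ix; }
                }
              }
            }
            out[w] = arg >= 0 ? best : 0.0;
            which[w] = (int)arg;  // input blocks stay below 2^31 voxels
            ++w;
          }
        }
      }
    }
  }
  return List::create(_["out"] = out, _["which"] = which,
                      _["odims"] = IntegerVector::create(o1, o2, o3, B, C));
}

// [[Rcpp::export]]
NumericVector maxpool3_bwd(NumericVector dout, IntegerVector which,
                           IntegerVector in_dims) {
  const R_xlen_t nin = (R_xlen_t)in_dims[0] * in_dims[1] * in_dims[2] *
                       in_dims[3] * in_dims[4];
  NumericVector dx(nin);
  const R_xlen_t n = dout.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    const int wi = which[i];
    if (wi >= 0) dx[wi] += dout[i];
  }
  return dx;
}

// [[Rcpp::export]]
NumericVector leaky_fwd(NumericVector x, double alpha) {
  const R_xlen_t n = x.size();
  NumericVector out(n);
  const double* px = x.begin();
  double* po = out.begin();
  for (R_xlen_t i = 0; i < n; ++i)
    po[i] = px[i] >= 0 ? px[i] : alpha * px[i];
  return out;
}

// Gradient through LeakyReLU given the *activation* values: the slope is
// 1 where act >= 0 and alpha elsewhere (alpha > 0 preserves the sign of
// the pre-activation, so the activation's sign identifies the branch).
// [[Rcpp::export]]
NumericVector leaky_bwd(NumericVector dout, NumericVector act,
                        double alpha) {
  const R_xlen_t n = dout.size();
  NumericVector out(n);
  const double* pd = dout.begin();
  const double* pa = act.begin();
  double* po = out.begin();
  for (R_xlen_t i = 0; i < n; ++i)
    po[i] = pa[i] >= 0 ? pd[i] : alpha * pd[i];
  return out;
}

// Fused in-place bias add + optional LeakyReLU on a freshly-computed GEMM
// result (one column per filter). The caller owns `pre` exclusively.
// [[Rcpp::export]]
void bias_act_inplace(NumericMatrix pre, NumericVector b, double alpha,
                      bool leaky) {
  const R_xlen_t nr = pre.nrow();
  const int nc = pre.ncol();
  double* p = pre.begin();
  for (int f = 0; f < nc; ++f) {
    const double bf = b[f];
    double* col = p + (R_xlen_t)f * nr;
    if (leaky) {
      for (R_xlen_t i = 0; i < nr; ++i) {
        const double v = col[i] + bf;
        col[i] = v >= 0 ? v : alpha * v;
      }
    } else {
      for (R_xlen_t i = 0; i < nr; ++i) col[i] += bf;
    }
  }
}
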