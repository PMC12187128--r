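// Low-level tensor primitives for the 3D convolutional network.
//
// Tensors are R numeric vectors in column-major order with layout
// (C, Z, Y, X): index(c,z,y,x) = c + C*(z + Z*(y + Y*x)), 0-based.
// 3x3x3 convolutions use zero padding 1 and are evaluated as
// im2col + GEMM (the GEMM runs in R through the installed BLAS).

#include <Rcpp.h>
using namespace Rcpp;

static inline int idx4(int c, int z, int y, int x, int C, int Z, int Y) {
  return c + C * (z + Z * (y + (long long)Y * x));
}

// Patch matrix for a contiguous block of voxel columns.
// Rows are ordered c fastest, then kz, ky, kx (kernel offsets in -1..1).
// Voxel linear index v = z + Z*(y + Y*x); columns are v = col_start .. col_start+ncols-1.
// [[Rcpp::export]]
NumericMatrix cpp_im2col3(NumericVector input, IntegerVector dims,
                          int col_start, int ncols) {
  const int C = dims[0], Z = dims[1], Y = dims[2], X = dims[3];
  NumericMatrix out(C * 27, ncols);
  double *po = out.begin();
  const double *pi = input.begin();
  for (int j = 0; j < ncols; ++j) {
    long long v = (long long)col_start + j;
    int z = (int)(v % Z);
    int y = (int)((v / Z) % Y);
    int x = (int)(v / ((long long)Z * Y));
    double *col = po + (long long)j * C * 27;
    int r = 0;
    for (int kx = -1; kx <= 1; ++kx) {
      int xx = x + kx;
      for (int ky = -1; ky <= 1; ++ky) {
        int yy = y + ky;
        for (int kz = -1; kz <= 1; ++kz) {
          int zz = z + kz;
          if (zz < 0 || zz >= Z || yy < 0 || yy >= Y || xx < 0 || xx >= X) {
            for (int c = 0; c < C; ++c) col[r++] = 0.0;
          } else {
            const double *src = pi + idx4(0, zz, yy, xx, C, Z, Y);
            for (int c = 0; c < C; ++c) col[r++] = src[c];
          }
        }
      }
    }
  }
  return out;
}

// Scatter-add of a patch-matrix gradient back onto the input tensor.
// `out` is modified in place (pre-allocated by the caller).
// [[Rcpp::export]]
void cpp_col2im3_add(NumericMatrix colgrad, IntegerVector dims,
                     int col_start, NumericVector out) {
  const int C = dims[0], Z = dims[1], Y = dims[2], X = dims[3];
  const int ncols = colgrad.ncol();
  double *po = out.begin();
  const double *pc = colgrad.begin();
  for (int j = 0; j < ncols; ++j) {
    long long v = (long long)col_start + j;
    int z = (int)(v % Z);
    int y = (int)((v / Z) % Y);
    int x = (int)(v / ((long long)Z * Y));
    const double *col = pc + (long long)j * C * 27;
    int r = 0;
    for (int kx = -1; kx <= 1; ++kx) {
      int xx = x + kx;
      for (int ky = -1; ky <= 1; ++ky) {
        int yy = y + ky;
        for (int kz = -1; kz <= 1; ++kz) {
          int zz = z + kz;
          if (zz < 0 || zz >= Z || yy < 0 || yy >= Y || xx < 0 || xx >= X) {
            r += C;
          } else {
            double *dst = po + idx4(0, zz, yy, xx, C, Z, Y);
            for (int c = 0; c < C; ++c) dst[c] += col[r++];
          }
        }
      }
    }
  }
}

// 2x2x2 max pooling with stride 2; spatial dims must be even.
// Returns the pooled tensor and the (0-based) argmax positions in the input.
// [[Rcpp::export]]
List cpp_maxpool2(NumericVector input, IntegerVector dims) {
  const int C = dims[0], Z = dims[1], Y = dims[2], X = dims[3];
  const int Zo = Z / 2, Yo = Y / 2, Xo = X / 2;
  NumericVector out((R_xlen_t)C * Zo * Yo * Xo);
  IntegerVector arg((R_xlen_t)C * Zo * Yo * Xo);
  const double *pi = input.begin();
  double *po = out.begin();
  int *pa = arg.begin();
  for (int x = 0; x < Xo; ++x)
    for (int y = 0; y < Yo; ++y)
      for (int z = 0; z < Zo; ++z)
        for (int c = 0; c < C; ++c) {
          double best = R_NegInf; int bi = -1;
          for (int kx = 0; kx < 2; ++kx)
            for (int ky = 0; ky < 2; ++ky)
              for (int kz = 0; kz < 2; ++kz) {
                int i = idx4(c, 2 * z + kz, 2 * y + ky, 2 * x + kx, C, Z, Y);
                if (pi[i] > best) { best = pi[i]; bi = i; }
              }
          int o = idx4(c, z, y, x, C, Zo, Yo);
          po[o] = best; pa[o] = bi;
        }
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_backward(NumericVector gradout, IntegerVector argmax,
                                    IntegerVector in_dims) {
  const R_xlen_t n = (R_xlen_t)in_dims[0] * in_dims[1] * in_dims[2] * in_dims[3];
  NumericVector gin(n);
  const double *pg = gradout.begin();
  const int *pa = argmax.begin();
  double *po = gin.begin();
  for (R_xlen_t i = 0; i < gradout.size(); ++i) po[pa[i]] += pg[i];
  return gin;
}

// Transposed 2x2x2 convolution, stride 2 (learned upsampling).
// Weight layout: w[co + Cout*(ci + Cin*(kz + 2*(ky + 2*kx)))].
// [[Rcpp::export]]
NumericVector cpp_upconv2_forward(NumericVector input, IntegerVector dims,
                                  NumericVector w, int Cout) {
  const int C = dims[0], Z = dims[1], Y = dims[2], X = dims[3];
  const int Zo = 2 * Z, Yo = 2 * Y, Xo = 2 * X;
  NumericVector out((R_xlen_t)Cout * Zo * Yo * Xo);
  const double *pi = input.begin(), *pw = w.begin();
  double *po = out.begin();
  for (int x = 0; x < X; ++x)
    for (int y = 0; y < Y; ++y)
      for (int z = 0; z < Z; ++z) {
        const double *in = pi + idx4(0, z, y, x, C, Z, Y);
        for (int kx = 0; kx < 2; ++kx)
          for (int ky = 0; ky < 2; ++ky)
            for (int kz = 0; kz < 2; ++kz) {
              double *dst = po + idx4(0, 2 * z + kz, 2 * y + ky, 2 * x + kx,
                                      Cout, Zo, Yo);
              const double *wk = pw + (R_xlen_t)Cout * C * (kz + 2 * (ky + 2 * kx));
              for (int ci = 0; ci < C; ++ci) {
                double v = in[ci];
                const double *wc = wk + (R_xlen_t)Cout * ci;
                for (int co = 0; co < Cout; ++co) dst[co] += v * wc[co];
              }
            }
      }
  return out;
}

// [[Rcpp::export]]
List cpp_upconv2_backward(NumericVector input, IntegerVector dims,
                          NumericVector w, int Cout, NumericVector gradout) {
  const int C = dims[0], Z = dims[1], Y = dims[2], X = dims[3];
  const int Zo = 2 * Z, Yo = 2 * Y;
  NumericVector gin((R_xlen_t)C * Z * Y * X);
  NumericVector gw((R_xlen_t)w.size());
  const double *pi = input.begin(), *pw = w.begin(), *pg = gradout.begin();
  double *pgi = gin.begin(), *pgw = gw.begin();
  for (int x = 0; x < X; ++x)
    for (int y = 0; y < Y; ++y)
      for (int z = 0; z < Z; ++z) {
        const double *in = pi + idx4(0, z, y, x, C, Z, Y);
        double *gi = pgi + idx4(0, z, y, x, C, Z, Y);
        for (int kx = 0; kx < 2; ++kx)
          for (int ky = 0; ky < 2; ++ky)
            for (int kz = 0; kz < 2; ++kz) {
              const double *go = pg + idx4(0, 2 * z + kz, 2 * y + ky,
                                           2 * x + kx, Cout, Zo, Yo);
              R_xlen_t koff = (R_xlen_t)Cout * C * (kz + 2 * (ky + 2 * kx));
              for (int ci = 0; ci < C; ++ci) {
                const double *wc = pw + koff + (R_xlen_t)Cout * ci;
                double *gwc = pgw + koff + (R_xlen_t)Cout * ci;
                double acc = 0.0, v = in[ci];
                for (int co = 0; co < Cout; ++co) {
                  acc += go[co] * wc[co];
                  gwc[co] += v * go[co];
                }
                gi[ci] += acc;
              }
            }
      }
  return List::create(_["grad_input"] = gin, _["grad_w"] = gw);
}
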