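// 3-D cross-correlation over the (electrode, band, frame) axes of a
// 5-axis tensor stored column-major as (batch, n1, n2, n3, channels).
// Implemented as im2col + BLAS dgemm: rows of the patch matrix are
// indexed (batch fastest, then the three output positions), so the
// GEMM result is laid out exactly like the output tensor.

#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif
#include <vector>

using namespace Rcpp;

struct ConvGeom {
  int B, N1, N2, N3, Ci;
  int P, Q, R, Co;
  int s1, s2, s3, p1, p2, p3;
  int O1, O2, O3;
  R_xlen_t rows, K;
};

static ConvGeom geom(const IntegerVector& xd, const IntegerVector& wd,
                     const IntegerVector& stride, const IntegerVector& pad) {
  ConvGeom g;
  g.B = xd[0]; g.N1 = xd[1]; g.N2 = xd[2]; g.N3 = xd[3]; g.Ci = xd[4];
  g.P = wd[0]; g.Q = wd[1]; g.R = wd[2]; g.Co = wd[4];
  g.s1 = stride[0]; g.s2 = stride[1]; g.s3 = stride[2];
  g.p1 = pad[0]; g.p2 = pad[1]; g.p3 = pad[2];
  g.O1 = (g.N1 + 2 * g.p1 - g.P) / g.s1 + 1;
  g.O2 = (g.N2 + 2 * g.p2 - g.Q) / g.s2 + 1;
  g.O3 = (g.N3 + 2 * g.p3 - g.R) / g.s3 + 1;
  if (g.O1 < 1 || g.O2 < 1 || g.O3 < 1)
    stop("kernel/stride exceed padded input extent");
  g.rows = (R_xlen_t)g.B * g.O1 * g.O2 * g.O3;
  g.K = (R_xlen_t)g.P * g.Q * g.R * g.Ci;
  return g;
}

// patch matrix: rows x (P*Q*R*Ci), zero-filled where padding reaches
// outside the input
static void im2col(const double* x, const ConvGeom& g, double* col) {
  R_xlen_t k = 0;
  for (int ci = 0; ci < g.Ci; ++ci)
    for (int r = 0; r < g.R; ++r)
      for (int q = 0; q < g.Q; ++q)
        for (int p = 0; p < g.P; ++p, ++k) {
          double* dst0 = col + k * g.rows;
          for (int o3 = 0; o3 < g.O3; ++o3) {
            const int i3 = o3 * g.s3 + r - g.p3;
            for (int o2 = 0; o2 < g.O2; ++o2) {
              const int i2 = o2 * g.s2 + q - g.p2;
              for (int o1 = 0; o1 < g.O1; ++o1) {
                const int i1 = o1 * g.s1 + p - g.p1;
                double* dst = dst0 + (R_xlen_t)g.B * (o1 + (R_xlen_t)g.O1 * (o2 + (R_xlen_t)g.O2 * o3));
                if (i1 < 0 || i1 >= g.N1 || i2 < 0 || i2 >= g.N2 ||
                    i3 < 0 || i3 >= g.N3) {
                  for (int b = 0; b < g.B; ++b) dst[b] = 0.0;
                } else {
                  const double* src = x + (R_xlen_t)g.B * (i1 + (R_xlen_t)g.N1 * (i2 + (R_xlen_t)g.N2 * (i3 + (R_xlen_t)g.N3 * ci)));
                  for (int b = 0; b < g.B; ++b) dst[b] = src[b];
                }
              }
            }
          }
        }
}

// scatter-add of a patch-matrix gradient back onto the input tensor
static void col2im(const double* col, const ConvGeom& g, double* dx) {
  R_xlen_t k = 0;
  for (int ci = 0; ci < g.Ci; ++ci)
    for (int r = 0; r < g.R; ++r)
      for (int q = 0; q < g.Q; ++q)
        for (int p = 0; p < g.P; ++p, ++k) {
          const double* src0 = col + k * g.rows;
          for (int o3 = 0; o3 < g.O3; ++o3) {
            const int i3 = o3 * g.s3 + r - g.p3;
            if (i3 < 0 || i3 >= g.N3) continue;
            for (int o2 = 0; o2 < g.O2; ++o2) {
              const int i2 = o2 * g.s2 + q - g.p2;
              if (i2 < 0 || i2 >= g.N2) continue;
              for (int o1 = 0; o1 < g.O1; ++o1) {
                const int i1 = o1 * g.s1 + p - g.p1;
                if (i1 < 0 || i1 >= g.N1) continue;
                const double* src = src0 + (R_xlen_t)g.B * (o1 + (R_xlen_t)g.O1 * (o2 + (R_xlen_t)g.O2 * o3));
                double* dst = dx + (R_xlen_t)g.B * (i1 + (R_xlen_t)g.N1 * (i2 + (R_xlen_t)g.N2 * (i3 + (R_xlen_t)g.N3 * ci)));
                for (int b = 0; b < g.B; ++b) dst[b] += src[b];
              }
            }
          }
        }
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_fwd(NumericVector x, IntegerVector xd,
                             NumericVector w, IntegerVector wd,
                             NumericVector bias,
                             IntegerVector stride, IntegerVector pad) {
  ConvGeom g = geom(xd, wd, stride, pad);
  std::vector<double> col(g.rows * g.K);
  im2col(x.begin(), g, col.data());
  NumericVector out(g.rows * g.Co);
  const int m = (int)g.rows, n = g.Co, k = (int)g.K;
  const double one = 1.0, zero = 0.0;
  F77_CALL(dgemm)("N", "N", &m, &n, &k, &one, col.data(), &m,
                  w.begin(), &k, &zero, out.begin(), &m FCONE FCONE);
  for (int co = 0; co < g.Co; ++co) {
    const double b0 = bias[co];
    if (b0 != 0.0) {
      double* dst = out.begin() + (R_xlen_t)co * g.rows;
      for (R_xlen_t i = 0; i < g.rows; ++i) dst[i] += b0;
    }
  }
  out.attr("dim") = IntegerVector::create(g.B, g.O1, g.O2, g.O3, g.Co);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_bwd_input(NumericVector dout, IntegerVector od,
                                   NumericVector w, IntegerVector wd,
                                   IntegerVector xd,
                                   IntegerVector stride, IntegerVector pad) {
  ConvGeom g = geom(xd, wd, stride, pad);
  std::vector<double> dcol(g.rows * g.K);
  const int m = (int)g.rows, n = (int)g.K, k = g.Co;
  const double one = 1.0, zero = 0.0;
  // dcol = dout %*% t(w)
  F77_CALL(dgemm)("N", "T", &m, &n, &k, &one, dout.begin(), &m,
                  w.begin(), &n, &zero, dcol.data(), &m FCONE FCONE);
  NumericVector dx((R_xlen_t)g.B * g.N1 * g.N2 * g.N3 * g.Ci);
  col2im(dcol.data(), g, dx.begin());
  dx.attr("dim") = IntegerVector::create(g.B, g.N1, g.N2, g.N3, g.Ci);
  return dx;
}

// [[Rcpp::export]]
List cpp_conv3d_bwd_weights(NumericVector x, IntegerVector xd,
                            NumericVector dout, IntegerVector od,
                            IntegerVector wd,
                            IntegerVector stride, IntegerVector pad) {
  ConvGeom g = geom(xd, wd, stride, pad);
  std::vector<double> col(g.rows * g.K);
  im2col(x.begin(), g, col.data());
  NumericVector dw(g.K * g.Co);
  const int m = (int)g.K, n = g.Co, k = (int)g.rows;
  const double one = 1.0, zero = 0.0;
  // dw = t(col) %*% dout
  F77_CALL(dgemm)("T", "N", &m, &n, &k, &one, col.data(), &k,
                  dout.begin(), &k, &zero, dw.begin(), &m FCONE FCONE);
  NumericVector db(g.Co);
  for (int co = 0; co < g.Co; ++co) {
    const double* src = dout.begin() + (R_xlen_t)co * g.rows;
    double acc = 0.0;
    for (R_xlen_t i = 0; i < g.rows; ++i) acc += src[i];
    db[co] = acc;
  }
  dw.attr("dim") = IntegerVector::create(g.P, g.Q, g.R, g.Ci, g.Co);
  return List::create(_["dw"] = dw, _["db"] = db);
}
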