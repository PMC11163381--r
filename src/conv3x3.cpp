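// 3x3 "same" convolution forward/backward, single precision.
//
// Tensor layout (R, column-major): activations (H, W, C, B), kernels
// (3, 3, Cin, Cout). Internally each sample is zero-padded by one pixel and
// flattened pixel-major into Xpad ((H+2)*(W+2)*B x C); the convolution is
// then nine row-shifted GEMMs (one per kernel offset), which keeps the work
// BLAS-bound without the 9x im2col memory blowup. Contributions that cross
// a sample's padding ring only ever land on padding rows, which are
// discarded on gather. Single precision is deliberate: tiles live in
// [-1, 1] and gradients feed Adam, so float32 GEMM (~4x faster than double
// here) costs nothing that matters on one CPU.

#define ARMA_NO_DEBUG
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

extern "C" void sgemm_(const char* transa, const char* transb, const int* m,
  const int* n, const int* k, const float* alpha, const float* a,
  const int* lda, const float* b, const int* ldb, const float* beta,
  float* c, const int* ldc);

static void sgemm(char ta, char tb, int m, int n, int k, float alpha,
                  const float* a, int lda, const float* b, int ldb,
                  float beta, float* c, int ldc) {
  sgemm_(&ta, &tb, &m, &n, &k, &alpha, a, &lda, b, &ldb, &beta, c, &ldc);
}

// Pack (H, W, C, B) doubles into padded pixel-major float (Lp*B x C),
// Lp = (H+2)*(W+2); pixel q = (h+1) + (H+2)*(w+1) within a sample.
static arma::fmat pack_pad(const double* x, int H, int W, int C, int B) {
  int Hp = H + 2, Wp = W + 2;
  size_t HW = (size_t)H * W, Lp = (size_t)Hp * Wp;
  arma::fmat xp(Lp * B, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    float* col = xp.colptr(c);
    for (int b = 0; b < B; ++b) {
      const double* src0 = x + HW * (c + (size_t)C * b);
      float* dst0 = col + Lp * b;
      for (int w = 0; w < W; ++w) {
        const double* src = src0 + (size_t)H * w;
        float* dst = dst0 + (w + 1) * (size_t)Hp + 1;
        for (int h = 0; h < H; ++h) dst[h] = (float)src[h];
      }
    }
  }
  return xp;
}

// Gather padded pixel-major (Lp*B x C) back to an (H, W, C, B) double array,
// dropping padding rows.
static NumericVector unpack(const arma::fmat& yp, int H, int W, int C, int B) {
  int Hp = H + 2, Wp = W + 2;
  size_t HW = (size_t)H * W, Lp = (size_t)Hp * Wp;
  NumericVector res(HW * C * B);
  res.attr("dim") = IntegerVector::create(H, W, C, B);
  double* rp = REAL(res);
  for (int c = 0; c < C; ++c) {
    const float* col = yp.colptr(c);
    for (int b = 0; b < B; ++b) {
      double* dst0 = rp + HW * (c + (size_t)C * b);
      const float* src0 = col + Lp * b;
      for (int w = 0; w < W; ++w) {
        double* dst = dst0 + (size_t)H * w;
        const float* src = src0 + (w + 1) * (size_t)Hp + 1;
        for (int h = 0; h < H; ++h) dst[h] = (double)src[h];
      }
    }
  }
  return res;
}

// Kernel slice k = (dh+1) + 3*(dw+1) as a Cin x Cout float matrix.
static arma::fmat kernel_slice(const double* w, int k, int Cin, int Cout) {
  arma::fmat Wk(Cin, Cout);
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < Cin; ++ci)
      Wk(ci, co) = (float)w[k + 9 * (ci + (size_t)Cin * co)];
  return Wk;
}

// Row shift of kernel offset (dh, dw) in the flattened padded frame.
static inline int offset_of(int k, int Hp) {
  int dh = k % 3 - 1, dw = k / 3 - 1;
  return dh + Hp * dw;
}

// [[Rcpp::export]]
NumericVector conv3x3_fwd(NumericVector x, NumericVector w, NumericVector bias) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  int Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv3x3_fwd: input has %d channels but kernel expects %d", C, Cin);
  int Hp = H + 2;
  size_t Lp = (size_t)Hp * (W + 2), P = Lp * B;
  arma::fmat xp = pack_pad(REAL(x), H, W, C, B);
  arma::fmat yp(P, Cout);
  arma::frowvec bf(Cout);
  for (int co = 0; co < Cout; ++co) bf(co) = (float)bias[co];
  yp.each_row() = bf;
  const double* wp = REAL(w);
  for (int k = 0; k < 9; ++k) {
    arma::fmat Wk = kernel_slice(wp, k, Cin, Cout);
    int off = offset_of(k, Hp);
    int lo = std::max(0, -off);
    int m = (int)P - std::abs(off);
    sgemm('N', 'N', m, Cout, Cin, 1.0f,
      xp.memptr() + lo + off, (int)P, Wk.memptr(), Cin,
      1.0f, yp.memptr() + lo, (int)P);
  }
  return unpack(yp, H, W, Cout, B);
}

// [[Rcpp::export]]
List conv3x3_bwd(NumericVector x, NumericVector w, NumericVector gy) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  int Cin = wd[2], Cout = wd[3];
  int Hp = H + 2;
  size_t Lp = (size_t)Hp * (W + 2), P = Lp * B;
  arma::fmat xp = pack_pad(REAL(x), H, W, C, B);
  arma::fmat gp = pack_pad(REAL(gy), H, W, Cout, B);
  arma::fmat gxp(P, Cin, arma::fill::zeros);
  const double* wp = REAL(w);
  NumericVector gw((size_t)9 * Cin * Cout);
  gw.attr("dim") = IntegerVector::create(3, 3, Cin, Cout);
  double* gwp = REAL(gw);
  arma::fmat gWk(Cin, Cout);
  for (int k = 0; k < 9; ++k) {
    arma::fmat Wk = kernel_slice(wp, k, Cin, Cout);
    int off = offset_of(k, Hp);
    int lo = std::max(0, -off);
    int m = (int)P - std::abs(off);
    // y rows [lo, lo+m) read x rows [lo+off, lo+off+m)
    sgemm('T', 'N', Cin, Cout, m, 1.0f,
      xp.memptr() + lo + off, (int)P, gp.memptr() + lo, (int)P,
      0.0f, gWk.memptr(), Cin);
    sgemm('N', 'T', m, Cin, Cout, 1.0f,
      gp.memptr() + lo, (int)P, Wk.memptr(), Cin,
      1.0f, gxp.memptr() + lo + off, (int)P);
    for (int co = 0; co < Cout; ++co)
      for (int ci = 0; ci < Cin; ++ci)
        gwp[k + 9 * (ci + (size_t)Cin * co)] = (double)gWk(ci, co);
  }
  NumericVector gb(Cout);
  for (int co = 0; co < Cout; ++co) {
    // padded rows of gy are zero, so the full-column sum is exact
    gb[co] = (double)arma::accu(gp.col(co));
  }
  List out = List::create(_["gx"] = unpack(gxp, H, W, Cin, B),
    _["gw"] = gw, _["gb"] = gb);
  return out;
}
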