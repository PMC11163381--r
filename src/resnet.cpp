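// Fused float-resident forward/backward for the residual noise predictor.
//
// The whole block stack runs on padded pixel-major float buffers
// ((H+2)*(W+2)*B x C), so activations never round-trip through R between
// layers. Convolutions are the same nine row-shifted sgemm calls as in
// conv3x3.cpp; after every convolution the one-pixel padding ring is
// re-zeroed so the next "same" convolution sees zero padding. The U-Net
// keeps the generic R path; this fast path exists because the residual
// backbone carries the training workload.

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

namespace {

struct Geom {
  int H, W, B, Hp, Wp;
  size_t Lp, P;   // padded pixels per sample, total padded pixels
};

// zero the padding ring of every sample in every channel
void zero_ring(arma::fmat& m, const Geom& g) {
  for (arma::uword c = 0; c < m.n_cols; ++c) {
    float* col = m.colptr(c);
    for (int b = 0; b < g.B; ++b) {
      float* s = col + g.Lp * b;
      std::fill(s, s + g.Hp, 0.0f);                        // first padded col
      std::fill(s + g.Lp - g.Hp, s + g.Lp, 0.0f);          // last padded col
      for (int w = 1; w <= g.W; ++w) {
        s[(size_t)g.Hp * w] = 0.0f;
        s[(size_t)g.Hp * w + g.Hp - 1] = 0.0f;
      }
    }
  }
}

arma::fmat pack(const double* x, const Geom& g, int C) {
  arma::fmat xp(g.P, C, arma::fill::zeros);
  size_t HW = (size_t)g.H * g.W;
  for (int c = 0; c < C; ++c) {
    float* col = xp.colptr(c);
    for (int b = 0; b < g.B; ++b) {
      const double* src0 = x + HW * (c + (size_t)C * b);
      float* dst0 = col + g.Lp * b;
      for (int w = 0; w < g.W; ++w) {
        const double* src = src0 + (size_t)g.H * w;
        float* dst = dst0 + (w + 1) * (size_t)g.Hp + 1;
        for (int h = 0; h < g.H; ++h) dst[h] = (float)src[h];
      }
    }
  }
  return xp;
}

NumericVector unpack(const arma::fmat& yp, const Geom& g, int C) {
  size_t HW = (size_t)g.H * g.W;
  NumericVector res(HW * C * g.B);
  res.attr("dim") = IntegerVector::create(g.H, g.W, C, g.B);
  double* rp = REAL(res);
  for (int c = 0; c < C; ++c) {
    const float* col = yp.colptr(c);
    for (int b = 0; b < g.B; ++b) {
      double* dst0 = rp + HW * (c + (size_t)C * b);
      const float* src0 = col + g.Lp * b;
      for (int w = 0; w < g.W; ++w) {
        double* dst = dst0 + (size_t)g.H * w;
        const float* src = src0 + (w + 1) * (size_t)g.Hp + 1;
        for (int h = 0; h < g.H; ++h) dst[h] = (double)src[h];
      }
    }
  }
  return res;
}

arma::fmat float_w(const NumericVector& w) {
  IntegerVector wd = w.attr("dim");
  arma::fmat Wm((size_t)9 * wd[2], wd[3]);
  const double* p = REAL(w);
  for (size_t i = 0; i < Wm.n_elem; ++i) Wm(i) = (float)p[i];
  return Wm;   // rows: k + 9*cin, cols: cout
}

inline int offset_of(int k, int Hp) {
  return (k % 3 - 1) + Hp * (k / 3 - 1);
}

// y (pre-allocated P x Cout) <- conv(x) + bias; ring zeroed afterwards
void conv_fwd(const arma::fmat& x, const arma::fmat& Wm,
              const NumericVector& bias, arma::fmat& y, const Geom& g) {
  int Cin = x.n_cols, Cout = y.n_cols;
  for (int co = 0; co < Cout; ++co) {
    float bf = (float)bias[co];
    float* c = y.colptr(co);
    std::fill(c, c + g.P, bf);
  }
  arma::fmat Wk(Cin, Cout);
  for (int k = 0; k < 9; ++k) {
    for (int co = 0; co < Cout; ++co)
      for (int ci = 0; ci < Cin; ++ci)
        Wk(ci, co) = Wm(k + 9 * ci, co);
    int off = offset_of(k, g.Hp);
    int lo = std::max(0, -off);
    int m = (int)g.P - std::abs(off);
    sgemm('N', 'N', m, Cout, Cin, 1.0f, x.memptr() + lo + off, (int)g.P,
      Wk.memptr(), Cin, 1.0f, y.memptr() + lo, (int)g.P);
  }
  zero_ring(y, g);
}

// gx += conv-backward(gy); gw/gb written to doubles. gy must have zero ring.
void conv_bwd(const arma::fmat& x, const arma::fmat& Wm, const arma::fmat& gy,
              arma::fmat* gx, double* gw, double* gb, const Geom& g) {
  int Cin = x.n_cols, Cout = gy.n_cols;
  arma::fmat Wk(Cin, Cout), gWk(Cin, Cout);
  for (int k = 0; k < 9; ++k) {
    for (int co = 0; co < Cout; ++co)
      for (int ci = 0; ci < Cin; ++ci)
        Wk(ci, co) = Wm(k + 9 * ci, co);
    int off = offset_of(k, g.Hp);
    int lo = std::max(0, -off);
    int m = (int)g.P - std::abs(off);
    sgemm('T', 'N', Cin, Cout, m, 1.0f, x.memptr() + lo + off, (int)g.P,
      gy.memptr() + lo, (int)g.P, 0.0f, gWk.memptr(), Cin);
    if (gx) {
      sgemm('N', 'T', m, Cin, Cout, 1.0f, gy.memptr() + lo, (int)g.P,
        Wk.memptr(), Cin, 1.0f, gx->memptr() + lo + off, (int)g.P);
    }
    for (int co = 0; co < Cout; ++co)
      for (int ci = 0; ci < Cin; ++ci)
        gw[k + 9 * (ci + (size_t)Cin * co)] = (double)gWk(ci, co);
  }
  for (int co = 0; co < Cout; ++co) {
    double s = 0;
    const float* c = gy.colptr(co);
    for (size_t p = 0; p < g.P; ++p) s += c[p];
    gb[co] = s;
  }
  if (gx) zero_ring(*gx, g);
}

// a = relu(a1 + tb), in place over a1's buffer copy
void bias_relu(const arma::fmat& a1, const NumericMatrix& tb, arma::fmat& a,
               const Geom& g) {
  int C = a1.n_cols;
  for (int c = 0; c < C; ++c) {
    const float* src = a1.colptr(c);
    float* dst = a.colptr(c);
    for (int b = 0; b < g.B; ++b) {
      float bias = (float)tb(c, b);
      const float* s = src + g.Lp * b;
      float* d = dst + g.Lp * b;
      for (size_t p = 0; p < g.Lp; ++p) {
        float v = s[p] + bias;
        d[p] = v > 0 ? v : 0;
      }
    }
  }
  zero_ring(a, g);  // ring held the bias through the relu; reset it
}

struct ResWS {
  Geom g;
  arma::fmat x;                    // packed network input
  std::vector<arma::fmat> h;       // h[0] = head output, h[i] post block i
  std::vector<arma::fmat> a;       // post-relu activation per block
  arma::fmat tail_in;
};

}  // namespace

// weights: list(head = list(w, b), blocks = list(list(conv1=list(w,b),
//   conv2=list(w,b))), tail = list(w, b)); tbs: list of (C x B) matrices.
// [[Rcpp::export]]
List resnet_fwd_cpp(NumericVector x, List weights, List tbs, bool train) {
  IntegerVector xd = x.attr("dim");
  Geom g;
  g.H = xd[0]; g.W = xd[1]; g.B = xd[3];
  g.Hp = g.H + 2; g.Wp = g.W + 2;
  g.Lp = (size_t)g.Hp * g.Wp; g.P = g.Lp * g.B;
  int Cin = xd[2];
  List head = weights["head"], blocks = weights["blocks"],
    tail = weights["tail"];
  int C = as<IntegerVector>(as<NumericVector>(head["w"]).attr("dim"))[3];
  int nb = blocks.size();

  Rcpp::XPtr<ResWS> ws(new ResWS(), true);
  ws->g = g;
  ws->x = pack(REAL(x), g, Cin);
  ws->h.resize(nb + 1);
  ws->a.resize(nb);

  arma::fmat Wh = float_w(head["w"]);
  ws->h[0].set_size(g.P, C);
  conv_fwd(ws->x, Wh, head["b"], ws->h[0], g);

  arma::fmat a1(g.P, C);
  for (int i = 0; i < nb; ++i) {
    List blk = blocks[i];
    List c1 = blk["conv1"], c2 = blk["conv2"];
    arma::fmat W1 = float_w(c1["w"]), W2 = float_w(c2["w"]);
    conv_fwd(ws->h[i], W1, c1["b"], a1, g);
    ws->a[i].set_size(g.P, C);
    bias_relu(a1, tbs[i], ws->a[i], g);
    ws->h[i + 1].set_size(g.P, C);
    conv_fwd(ws->a[i], W2, c2["b"], ws->h[i + 1], g);
    ws->h[i + 1] += ws->h[i];          // identity skip (rings stay zero)
  }
  ws->tail_in = ws->h[nb] + ws->h[0];  // global skip
  arma::fmat Wt = float_w(tail["w"]);
  int Cout = as<IntegerVector>(as<NumericVector>(tail["w"]).attr("dim"))[3];
  arma::fmat out(g.P, Cout);
  conv_fwd(ws->tail_in, Wt, tail["b"], out, g);
  List res = List::create(_["out"] = unpack(out, g, Cout));
  if (train) res["ws"] = ws;
  return res;
}

// [[Rcpp::export]]
List resnet_bwd_cpp(SEXP ws_ptr, List weights, NumericVector gout) {
  Rcpp::XPtr<ResWS> ws(ws_ptr);
  const Geom& g = ws->g;
  List head = weights["head"], blocks = weights["blocks"],
    tail = weights["tail"];
  int nb = blocks.size();
  int C = ws->h[0].n_cols;
  int Cout = as<IntegerVector>(as<NumericVector>(tail["w"]).attr("dim"))[2 + 1];
  int Cin = ws->x.n_cols;

  arma::fmat gO = pack(REAL(gout), g, Cout);

  NumericVector tail_gw((size_t)9 * C * Cout);
  tail_gw.attr("dim") = IntegerVector::create(3, 3, C, Cout);
  NumericVector tail_gb(Cout);
  arma::fmat g_h(g.P, C, arma::fill::zeros);
  arma::fmat Wt = float_w(tail["w"]);
  conv_bwd(ws->tail_in, Wt, gO, &g_h, REAL(tail_gw), REAL(tail_gb), g);

  arma::fmat g_h0 = g_h;   // global-skip branch
  List block_grads(nb);
  arma::fmat g_a(g.P, C), g_apre(g.P, C), g_hin(g.P, C);
  for (int i = nb - 1; i >= 0; --i) {
    List blk = blocks[i];
    List c1 = blk["conv1"], c2 = blk["conv2"];
    arma::fmat W1 = float_w(c1["w"]), W2 = float_w(c2["w"]);
    NumericVector gw2((size_t)9 * C * C), gb2(C), gw1((size_t)9 * C * C), gb1(C);
    gw2.attr("dim") = IntegerVector::create(3, 3, C, C);
    gw1.attr("dim") = IntegerVector::create(3, 3, C, C);
    g_a.zeros();
    conv_bwd(ws->a[i], W2, g_h, &g_a, REAL(gw2), REAL(gb2), g);
    // relu mask: a > 0 (a stored post-relu); per-(c,b) sums give the time bias grad
    NumericMatrix gtb(C, g.B);
    for (int c = 0; c < C; ++c) {
      const float* av = ws->a[i].colptr(c);
      const float* gv = g_a.colptr(c);
      float* dv = g_apre.colptr(c);
      for (int b = 0; b < g.B; ++b) {
        double acc = 0;
        const float* as = av + g.Lp * b;
        const float* gs = gv + g.Lp * b;
        float* ds = dv + g.Lp * b;
        for (size_t p = 0; p < g.Lp; ++p) {
          float v = as[p] > 0 ? gs[p] : 0.0f;
          ds[p] = v;
          acc += v;
        }
        gtb(c, b) = acc;
      }
    }
    g_hin.zeros();
    conv_bwd(ws->h[i], W1, g_apre, &g_hin, REAL(gw1), REAL(gb1), g);
    g_h += g_hin;            // identity skip joins the conv path
    block_grads[i] = List::create(
      _["conv1"] = List::create(_["w"] = gw1, _["b"] = gb1),
      _["conv2"] = List::create(_["w"] = gw2, _["b"] = gb2),
      _["gtb"] = gtb);
  }
  g_h0 += g_h;               // the stack's input is the head output
  NumericVector head_gw((size_t)9 * Cin * C), head_gb(C);
  head_gw.attr("dim") = IntegerVector::create(3, 3, Cin, C);
  conv_bwd(ws->x, float_w(head["w"]), g_h0, nullptr, REAL(head_gw),
    REAL(head_gb), g);
  return List::create(
    _["head"] = List::create(_["w"] = head_gw, _["b"] = head_gb),
    _["blocks"] = block_grads,
    _["tail"] = List::create(_["w"] = tail_gw, _["b"] = tail_gb));
}
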