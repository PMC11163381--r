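// Fused elementwise helpers for the residual blocks: adding the per-channel
// time bias and applying the nonlinearity in one pass avoids materializing
// intermediate (H, W, C, B) arrays in R on the training hot path.

#include <Rcpp.h>
using namespace Rcpp;

static inline double silu(double v) { return v / (1.0 + std::exp(-v)); }
static inline double dsilu(double v) {
  double s = 1.0 / (1.0 + std::exp(-v));
  return s * (1.0 + v * (1.0 - s));
}

// act: 0 = relu, 1 = silu. x is the conv output (pre-bias), tb is (C x B).
// [[Rcpp::export]]
NumericVector bias_act_fwd(NumericVector x, NumericMatrix tb, int act) {
  IntegerVector d = x.attr("dim");
  size_t HW = (size_t)d[0] * d[1];
  int C = d[2], B = d[3];
  NumericVector y(x.size());
  y.attr("dim") = d;
  const double* xp = REAL(x);
  double* yp = REAL(y);
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      double bias = tb(c, b);
      const double* xs = xp + HW * (c + (size_t)C * b);
      double* ys = yp + HW * (c + (size_t)C * b);
      if (act == 0) {
        for (size_t p = 0; p < HW; ++p) {
          double v = xs[p] + bias;
          ys[p] = v > 0 ? v : 0;
        }
      } else {
        for (size_t p = 0; p < HW; ++p) ys[p] = silu(xs[p] + bias);
      }
    }
  return y;
}

// Backward of bias_act_fwd: gx = gy * act'(x + tb), gtb = per-(c, b) sums.
// [[Rcpp::export]]
List bias_act_bwd(NumericVector x, NumericMatrix tb, NumericVector gy, int act) {
  IntegerVector d = x.attr("dim");
  size_t HW = (size_t)d[0] * d[1];
  int C = d[2], B = d[3];
  NumericVector gx(x.size());
  gx.attr("dim") = d;
  NumericMatrix gtb(C, B);
  const double* xp = REAL(x);
  const double* gp = REAL(gy);
  double* op = REAL(gx);
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      double bias = tb(c, b);
      size_t base = HW * (c + (size_t)C * b);
      const double* xs = xp + base;
      const double* gs = gp + base;
      double* os = op + base;
      double acc = 0;
      if (act == 0) {
        for (size_t p = 0; p < HW; ++p) {
          double g = (xs[p] + bias) > 0 ? gs[p] : 0;
          os[p] = g;
          acc += g;
        }
      } else {
        for (size_t p = 0; p < HW; ++p) {
          double g = gs[p] * dsilu(xs[p] + bias);
          os[p] = g;
          acc += g;
        }
      }
      gtb(c, b) = acc;
    }
  return List::create(_["gx"] = gx, _["gtb"] = gtb);
}
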