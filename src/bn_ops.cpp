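// One-pass per-channel helpers for batch normalization and the rectifier on
// (H, W, C, N) arrays: channel c of sample n occupies a contiguous H*W block.
#include <Rcpp.h>
using namespace Rcpp;

static void chan_dims(const NumericVector& x, int& hw, int& C, int& N) {
  IntegerVector d = x.attr("dim");
  hw = d[0] * d[1];
  C = d[2];
  N = d[3];
}

// per-channel sum and sum of squares
// [[Rcpp::export]]
List cpp_bn_moments(NumericVector x) {
  int hw, C, N;
  chan_dims(x, hw, C, N);
  NumericVector s(C), ss(C);
  const double* p = x.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      double a = 0, b = 0;
      for (int t = 0; t < hw; ++t) {
        const double v = *p++;
        a += v;
        b += v * v;
      }
      s[c] += a;
      ss[c] += b;
    }
  }
  return List::create(Named("sum") = s, Named("sumsq") = ss);
}

// per-channel sums of dy and dy * x
// [[Rcpp::export]]
List cpp_bn_dots(NumericVector dy, NumericVector x) {
  int hw, C, N;
  chan_dims(x, hw, C, N);
  NumericVector s(C), sx(C);
  const double* p = dy.begin();
  const double* q = x.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      double a = 0, b = 0;
      for (int t = 0; t < hw; ++t) {
        a += *p;
        b += (*p) * (*q);
        ++p;
        ++q;
      }
      s[c] += a;
      sx[c] += b;
    }
  }
  return List::create(Named("sum_dy") = s, Named("sum_dyx") = sx);
}

// y = x * a[c] + b[c]
// [[Rcpp::export]]
NumericVector cpp_scale_shift(NumericVector x, NumericVector a,
                              NumericVector b) {
  int hw, C, N;
  chan_dims(x, hw, C, N);
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const double* p = x.begin();
  double* o = y.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double ac = a[c], bc = b[c];
      for (int t = 0; t < hw; ++t) *o++ = (*p++) * ac + bc;
    }
  }
  return y;
}

// dx = dy * a[c] + x * b[c] + c0[c]  (batch-norm input gradient)
// [[Rcpp::export]]
NumericVector cpp_axpb(NumericVector dy, NumericVector x, NumericVector a,
                       NumericVector b, NumericVector c0) {
  int hw, C, N;
  chan_dims(x, hw, C, N);
  NumericVector out(x.size());
  out.attr("dim") = x.attr("dim");
  const double* p = dy.begin();
  const double* q = x.begin();
  double* o = out.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double ac = a[c], bc = b[c], cc = c0[c];
      for (int t = 0; t < hw; ++t) *o++ = (*p++) * ac + (*q++) * bc + cc;
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_relu_fwd(NumericVector x) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const double* p = x.begin();
  double* o = y.begin();
  const R_xlen_t m = x.size();
  for (R_xlen_t t = 0; t < m; ++t) o[t] = p[t] > 0 ? p[t] : 0;
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_relu_bwd(NumericVector dy, NumericVector y) {
  NumericVector out(dy.size());
  out.attr("dim") = dy.attr("dim");
  const double* p = dy.begin();
  const double* q = y.begin();
  double* o = out.begin();
  const R_xlen_t m = dy.size();
  for (R_xlen_t t = 0; t < m; ++t) o[t] = q[t] > 0 ? p[t] : 0;
  return out;
}
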