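// Low-level kernels for 2-D convolution and max-pooling on (H, W, C, N)
// column-major arrays. Convolutions are lowered to batch-level im2col + one
// GEMM over the whole mini-batch so the heavy lifting happens inside BLAS and
// large filter banks (Conv6) are streamed through memory once.
#include <RcppArmadillo.h>
using namespace Rcpp;

// Fill rows [n*OH*OW, (n+1)*OH*OW) of cols ((OH*OW*N) x (kh*kw*C)) from
// sample n. Row r = oh + OH*ow + OH*OW*n, column q = i + kh*j + kh*kw*c.
static void im2col_fill(const double* x, int H, int W, int C,
                        int kh, int kw, int stride, int pad,
                        int OH, int OW, arma::mat& cols,
                        std::size_t row_offset) {
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (std::size_t)H * W * c;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const int q = i + kh * j + kh * kw * c;
        double* col = cols.colptr(q) + row_offset;
        for (int ow = 0; ow < OW; ++ow) {
          const int iw = ow * stride - pad + j;
          double* dst = col + (std::size_t)OH * ow;
          if (iw < 0 || iw >= W) {
            std::fill(dst, dst + OH, 0.0);
            continue;
          }
          const double* xcol = xc + (std::size_t)H * iw;
          for (int oh = 0; oh < OH; ++oh) {
            const int ih = oh * stride - pad + i;
            dst[oh] = (ih >= 0 && ih < H) ? xcol[ih] : 0.0;
          }
        }
      }
    }
  }
}

// scatter-add of sample n's rows of dcols back onto the input gradient
static void col2im_acc(const arma::mat& dcols, double* dx, int H, int W, int C,
                       int kh, int kw, int stride, int pad, int OH, int OW,
                       std::size_t row_offset) {
  for (int c = 0; c < C; ++c) {
    double* xc = dx + (std::size_t)H * W * c;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const int q = i + kh * j + kh * kw * c;
        const double* col = dcols.colptr(q) + row_offset;
        for (int ow = 0; ow < OW; ++ow) {
          const int iw = ow * stride - pad + j;
          if (iw < 0 || iw >= W) continue;
          const double* src = col + (std::size_t)OH * ow;
          double* xcol = xc + (std::size_t)H * iw;
          for (int oh = 0; oh < OH; ++oh) {
            const int ih = oh * stride - pad + i;
            if (ih >= 0 && ih < H) xcol[ih] += src[oh];
          }
        }
      }
    }
  }
}

static void conv_dims(const IntegerVector& xd, const IntegerVector& wd,
                      int stride, int pad, int& OH, int& OW) {
  if (wd[2] != xd[2]) stop("filter depth does not match input channels");
  OH = (xd[0] + 2 * pad - wd[0]) / stride + 1;
  OW = (xd[1] + 2 * pad - wd[1]) / stride + 1;
  if (OH < 1 || OW < 1) stop("kernel larger than padded input");
}

// [[Rcpp::export]]
NumericVector cpp_conv_fwd(NumericVector x, NumericVector w, NumericVector b,
                           int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], F = wd[3];
  int OH, OW;
  conv_dims(xd, wd, stride, pad, OH, OW);
  const std::size_t patch = (std::size_t)kh * kw * C;
  const std::size_t plane = (std::size_t)OH * OW;

  const arma::mat Wm(w.begin(), patch, F, false, true);
  arma::mat cols(plane * N, patch);
  for (int n = 0; n < N; ++n) {
    im2col_fill(x.begin() + (std::size_t)H * W * C * n, H, W, C,
                kh, kw, stride, pad, OH, OW, cols, plane * n);
  }
  arma::mat Y = cols * Wm;  // (plane*N) x F

  NumericVector y((R_xlen_t)plane * F * N);
  y.attr("dim") = IntegerVector::create(OH, OW, F, N);
  double* yp = y.begin();
  for (int n = 0; n < N; ++n) {
    for (int f = 0; f < F; ++f) {
      const double* src = Y.colptr(f) + plane * n;
      double* dst = yp + plane * f + plane * F * n;
      const double bf = b[f];
      for (std::size_t t = 0; t < plane; ++t) dst[t] = src[t] + bf;
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv_bwd(NumericVector x, NumericVector w, NumericVector dy,
                  int stride, int pad, bool need_dx, bool need_dw) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], F = wd[3];
  int OH, OW;
  conv_dims(xd, wd, stride, pad, OH, OW);
  const std::size_t patch = (std::size_t)kh * kw * C;
  const std::size_t plane = (std::size_t)OH * OW;
  const arma::mat Wm(w.begin(), patch, F, false, true);

  // gather dy into the (plane*N) x F row-block layout used by im2col
  arma::mat DY(plane * N, F);
  const double* dyp = dy.begin();
  for (int n = 0; n < N; ++n) {
    for (int f = 0; f < F; ++f) {
      const double* src = dyp + plane * f + plane * F * n;
      std::copy(src, src + plane, DY.colptr(f) + plane * n);
    }
  }

  List out = List::create(Named("dx") = R_NilValue,
                          Named("dw") = R_NilValue,
                          Named("db") = R_NilValue);
  if (need_dw) {
    arma::mat cols(plane * N, patch);
    for (int n = 0; n < N; ++n) {
      im2col_fill(x.begin() + (std::size_t)H * W * C * n, H, W, C,
                  kh, kw, stride, pad, OH, OW, cols, plane * n);
    }
    NumericVector dwv((R_xlen_t)patch * F);
    dwv.attr("dim") = IntegerVector::create(kh, kw, C, F);
    arma::mat dW(dwv.begin(), patch, F, false, true);
    dW = cols.t() * DY;  // single GEMM straight into the result
    arma::rowvec db = arma::sum(DY, 0);
    out["dw"] = dwv;
    out["db"] = NumericVector(db.begin(), db.end());
  }
  if (need_dx) {
    NumericVector dx((R_xlen_t)H * W * C * N);
    dx.attr("dim") = IntegerVector::create(H, W, C, N);
    arma::mat dcols = DY * Wm.t();
    for (int n = 0; n < N; ++n) {
      col2im_acc(dcols, dx.begin() + (std::size_t)H * W * C * n,
                 H, W, C, kh, kw, stride, pad, OH, OW, plane * n);
    }
    out["dx"] = dx;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector x, int k, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int OH = (H + 2 * pad - k) / stride + 1;
  const int OW = (W + 2 * pad - k) / stride + 1;
  if (OH < 1 || OW < 1) stop("pooling window larger than padded input");

  NumericVector y((R_xlen_t)OH * OW * C * N);
  y.attr("dim") = IntegerVector::create(OH, OW, C, N);
  IntegerVector idx(y.size());  // 0-based flat index into x of the argmax
  const double* xp = x.begin();
  double* yp = y.begin();
  int* ip = idx.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const std::size_t base = (std::size_t)H * W * (c + (std::size_t)C * n);
      for (int ow = 0; ow < OW; ++ow) {
        for (int oh = 0; oh < OH; ++oh) {
          double best = -std::numeric_limits<double>::infinity();
          std::size_t bi = 0;
          for (int j = 0; j < k; ++j) {
            const int iw = ow * stride - pad + j;
            if (iw < 0 || iw >= W) continue;
            for (int i = 0; i < k; ++i) {
              const int ih = oh * stride - pad + i;
              if (ih < 0 || ih >= H) continue;
              const std::size_t fi = base + ih + (std::size_t)H * iw;
              if (xp[fi] > best) { best = xp[fi]; bi = fi; }
            }
          }
          const std::size_t oo = (std::size_t)oh + OH * ow +
            (std::size_t)OH * OW * (c + (std::size_t)C * n);
          yp[oo] = best;
          ip[oo] = (int)bi;
        }
      }
    }
  }
  return List::create(Named("y") = y, Named("idx") = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(NumericVector dy, IntegerVector idx,
                              IntegerVector xdim) {
  NumericVector dx((R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  dx.attr("dim") = xdim;
  double* dxp = dx.begin();
  const double* dyp = dy.begin();
  const int* ip = idx.begin();
  const R_xlen_t m = dy.size();
  for (R_xlen_t t = 0; t < m; ++t) dxp[ip[t]] += dyp[t];
  return dx;
}
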