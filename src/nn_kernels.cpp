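// Convolution and pooling kernels for the encoder/decoder networks.
// Tensors follow R's column-major layout: images are (H, W, C, N) arrays,
// conv weights are (k, k, Cin, Cout).  im2col over the whole minibatch,
// then a single GEMM per batch.

#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_size(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// Fill one sample's block of `cols` (k*k*Cin rows, Ho*Wo columns starting at
// column col0).  Row index = kh + k*kw + k*k*ci ; column index = ho + Ho*wo.
static void im2col(const double* x, int H, int W, int C,
                   int k, int stride, int pad, int Ho, int Wo,
                   arma::mat& cols, size_t col0) {
  const size_t R = cols.n_rows;
  for (int ci = 0; ci < C; ++ci) {
    const double* xc = x + (size_t)ci * H * W;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const size_t row = kh + (size_t)k * kw + (size_t)k * k * ci;
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * stride - pad + kw;
          double* dst = cols.memptr() + (col0 + (size_t)Ho * wo) * R + row;
          if (wi < 0 || wi >= W) continue;
          const double* xcol = xc + (size_t)wi * H;
          // valid ho range: 0 <= ho*stride - pad + kh < H
          int lo = 0, hi = Ho - 1;
          if (pad - kh > 0) lo = (pad - kh + stride - 1) / stride;
          while (hi >= lo && hi * stride - pad + kh >= H) --hi;
          for (int ho = lo; ho <= hi; ++ho)
            dst[(size_t)ho * R] = xcol[ho * stride - pad + kh];
        }
      }
    }
  }
}

// Scatter-add one sample's block of `cols` back into its gradient (col2im).
static void col2im(const arma::mat& cols, size_t col0, int H, int W, int C,
                   int k, int stride, int pad, int Ho, int Wo, double* gx) {
  const size_t R = cols.n_rows;
  for (int ci = 0; ci < C; ++ci) {
    double* gc = gx + (size_t)ci * H * W;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const size_t row = kh + (size_t)k * kw + (size_t)k * k * ci;
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * stride - pad + kw;
          if (wi < 0 || wi >= W) continue;
          const double* src = cols.memptr() + (col0 + (size_t)Ho * wo) * R + row;
          double* gcol = gc + (size_t)wi * H;
          int lo = 0, hi = Ho - 1;
          if (pad - kh > 0) lo = (pad - kh + stride - 1) / stride;
          while (hi >= lo && hi * stride - pad + kh >= H) --hi;
          for (int ho = lo; ho <= hi; ++ho)
            gcol[ho * stride - pad + kh] += src[(size_t)ho * R];
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w,
                             NumericVector b, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d: channel mismatch (input %d, weight %d)", C, Cin);
  const int Ho = out_size(H, k, stride, pad);
  const int Wo = out_size(W, k, stride, pad);
  if (Ho < 1 || Wo < 1) stop("conv2d: output size would be empty");

  const arma::mat Wmat(const_cast<double*>(w.begin()), (size_t)k * k * Cin,
                       Cout, false, true);

  NumericVector y((size_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);

  const size_t hw = (size_t)Ho * Wo;
  arma::mat cols((size_t)k * k * Cin, hw * N, arma::fill::zeros);
  for (int n = 0; n < N; ++n)
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, k, stride, pad,
           Ho, Wo, cols, hw * n);
  arma::mat Y = cols.t() * Wmat;            // (N*Ho*Wo) x Cout
  const double* bp = b.begin();
  const bool has_b = b.size() == (R_xlen_t)Cout;
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      const double* src = Y.colptr(co) + hw * n;
      double* dst = y.begin() + ((size_t)n * Cout + co) * hw;
      if (has_b && bp[co] != 0.0)
        for (size_t i = 0; i < hw; ++i) dst[i] = src[i] + bp[co];
      else
        std::memcpy(dst, src, hw * sizeof(double));
    }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector gy,
                    int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  IntegerVector gd = gy.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[3];
  const int Ho = gd[0], Wo = gd[1];
  const size_t hw = (size_t)Ho * Wo;

  const arma::mat Wmat(const_cast<double*>(w.begin()), (size_t)k * k * C,
                       Cout, false, true);

  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = xd;
  NumericVector gw((size_t)k * k * C * Cout);
  gw.attr("dim") = wd;
  NumericVector gb(Cout);

  arma::mat cols((size_t)k * k * C, hw * N, arma::fill::zeros);
  for (int n = 0; n < N; ++n)
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, k, stride, pad,
           Ho, Wo, cols, hw * n);

  // reorder gy (Ho,Wo,Cout,N) into (N*Ho*Wo) x Cout
  arma::mat gY(hw * N, Cout);
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co)
      std::memcpy(gY.colptr(co) + hw * n,
                  gy.begin() + ((size_t)n * Cout + co) * hw,
                  hw * sizeof(double));

  arma::mat gWmat(gw.begin(), (size_t)k * k * C, Cout, false, true);
  gWmat = cols * gY;
  arma::mat gcols = Wmat * gY.t();          // (k*k*C) x (N*Ho*Wo)
  for (int n = 0; n < N; ++n)
    col2im(gcols, hw * n, H, W, C, k, stride, pad, Ho, Wo,
           gx.begin() + (size_t)n * H * W * C);
  for (int co = 0; co < Cout; ++co)
    gb[co] = arma::accu(gY.col(co));
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Separable symmetric same-padding convolution (zero borders) of a stack of
// single-channel images (H, W, N) with a 1-D kernel: rows pass then columns
// pass.  Used for the simulator's Gaussian blur.
// [[Rcpp::export]]
NumericVector cpp_sepconv_same(NumericVector x, NumericVector kvec) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], N = xd.size() > 2 ? xd[2] : 1;
  const int K = kvec.size(), half = (K - 1) / 2;
  NumericVector y((size_t)H * W * N);
  y.attr("dim") = xd;
  std::vector<double> tmp((size_t)H * W);
  const double* kv = kvec.begin();
  for (int n = 0; n < N; ++n) {
    const double* xs = x.begin() + (size_t)n * H * W;
    double* ys = y.begin() + (size_t)n * H * W;
    std::fill(tmp.begin(), tmp.end(), 0.0);
    // vertical pass (along rows within a column)
    for (int w = 0; w < W; ++w) {
      const double* xc = xs + (size_t)w * H;
      double* tc = tmp.data() + (size_t)w * H;
      for (int t = -half; t <= half; ++t) {
        const double kvw = kv[t + half];
        const int lo = std::max(0, -t), hi = std::min(H, H - t);
        for (int h = lo; h < hi; ++h) tc[h] += kvw * xc[h + t];
      }
    }
    // horizontal pass (across columns)
    std::memset(ys, 0, (size_t)H * W * sizeof(double));
    for (int w = 0; w < W; ++w) {
      double* yc = ys + (size_t)w * H;
      for (int t = -half; t <= half; ++t) {
        const int ww = w + t;
        if (ww < 0 || ww >= W) continue;
        const double kvw = kv[t + half];
        const double* tc = tmp.data() + (size_t)ww * H;
        for (int h = 0; h < H; ++h) yc[h] += kvw * tc[h];
      }
    }
  }
  return y;
}

// 2x2 max pooling, stride 2.  Returns pooled values and the flat (1-based)
// argmax index into the input array, for the backward pass.
// [[Rcpp::export]]
List cpp_maxpool2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * N);
  IntegerVector idx((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  idx.attr("dim") = IntegerVector::create(Ho, Wo, C, N);

  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t base = ((size_t)n * C + c) * H * W;
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double best = -std::numeric_limits<double>::infinity();
          size_t bi = 0;
          for (int dw = 0; dw < 2; ++dw)
            for (int dh = 0; dh < 2; ++dh) {
              const size_t i = base + (size_t)(2 * wo + dw) * H +
                               (2 * ho + dh);
              if (x[i] > best) { best = x[i]; bi = i; }
            }
          const size_t oi = (((size_t)n * C + c) * Wo + wo) * Ho + ho;
          y[oi] = best;
          idx[oi] = (int)(bi + 1);
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bwd(IntegerVector idx, NumericVector gy,
                               IntegerVector xdim) {
  size_t nx = (size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector gx(nx);
  gx.attr("dim") = xdim;
  const R_xlen_t m = gy.size();
  for (R_xlen_t i = 0; i < m; ++i) gx[idx[i] - 1] += gy[i];
  return gx;
}
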