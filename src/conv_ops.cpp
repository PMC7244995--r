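// GEMM-based 2-D convolution primitives for the VAE.
//
// Array layout everywhere: column-major [H, W, C, N] (R array order,
// row index fastest). Weights: [kh, kw, Cin, Cout]. Output sizes use
// Ho = floor((H + 2*pad - kh)/stride) + 1; the transposed convolution is
// realized as conv_backward_data with an explicit output size, which
// subsumes output padding.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static void im2col(const double* x, int H, int W, int C,
                   int kh, int kw, int stride, int pad,
                   int Ho, int Wo, arma::mat& cols) {
  const int L = Ho * Wo;
  cols.zeros();
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)H * W * c;
    for (int dw = 0; dw < kw; ++dw) {
      for (int dh = 0; dh < kh; ++dh) {
        const int r = dh + kh * (dw + kw * c);
        double* colr = cols.memptr() + r; // stride K between columns
        const int K = cols.n_rows;
        for (int wo = 0; wo < Wo; ++wo) {
          const int w = wo * stride + dw - pad;
          if (w < 0 || w >= W) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            const int h = ho * stride + dh - pad;
            if (h < 0 || h >= H) continue;
            colr[(size_t)K * (ho + Ho * wo)] = xc[h + (size_t)H * w];
          }
        }
      }
    }
  }
}

static void col2im(const arma::mat& cols, int H, int W, int C,
                   int kh, int kw, int stride, int pad,
                   int Ho, int Wo, double* dx) {
  const int K = cols.n_rows;
  for (int c = 0; c < C; ++c) {
    double* xc = dx + (size_t)H * W * c;
    for (int dw = 0; dw < kw; ++dw) {
      for (int dh = 0; dh < kh; ++dh) {
        const int r = dh + kh * (dw + kw * c);
        const double* colr = cols.memptr() + r;
        for (int wo = 0; wo < Wo; ++wo) {
          const int w = wo * stride + dw - pad;
          if (w < 0 || w >= W) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            const int h = ho * stride + dh - pad;
            if (h < 0 || h >= H) continue;
            xc[h + (size_t)H * w] += colr[(size_t)K * (ho + Ho * wo)];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".cpp_conv2d_forward")]]
NumericVector cpp_conv2d_forward(NumericVector x, NumericVector w,
                                 NumericVector b, int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d: channel mismatch (%d vs %d)", Cin, C);
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  const int K = kh * kw * C, L = Ho * Wo;

  NumericVector y((size_t)L * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);

  arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  arma::rowvec bv(const_cast<double*>(b.begin()), Cout, false, true);
  arma::mat cols(K, L);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, kh, kw, stride, pad,
           Ho, Wo, cols);
    arma::mat yt(y.begin() + (size_t)L * Cout * n, L, Cout, false, true);
    yt = cols.t() * Wm;
    yt.each_row() += bv;
  }
  return y;
}

// dy: [Ho, Wo, Cout, N]; returns dx of explicit size [H, W, Cin, N].
// [[Rcpp::export(name = ".cpp_conv2d_backward_data")]]
NumericVector cpp_conv2d_backward_data(NumericVector dy, NumericVector w,
                                       int H, int W, int stride, int pad) {
  IntegerVector yd = dy.attr("dim"), wd = w.attr("dim");
  const int Ho = yd[0], Wo = yd[1], Cout = yd[2], N = yd[3];
  const int kh = wd[0], kw = wd[1], Cin = wd[2];
  if (wd[3] != Cout) stop("conv2d backward: filter count mismatch");
  const int K = kh * kw * Cin, L = Ho * Wo;

  NumericVector dx((size_t)H * W * Cin * N);
  dx.attr("dim") = IntegerVector::create(H, W, Cin, N);
  arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  arma::mat dcols(K, L);
  for (int n = 0; n < N; ++n) {
    arma::mat dyt(const_cast<double*>(dy.begin()) + (size_t)L * Cout * n,
                  L, Cout, false, true);
    dcols = Wm * dyt.t();
    col2im(dcols, H, W, Cin, kh, kw, stride, pad, Ho, Wo,
           dx.begin() + (size_t)H * W * Cin * n);
  }
  return dx;
}

// [[Rcpp::export(name = ".cpp_conv2d_backward_filter")]]
List cpp_conv2d_backward_filter(NumericVector x, NumericVector dy,
                                int kh, int kw, int stride, int pad) {
  IntegerVector xd = x.attr("dim"), yd = dy.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = yd[0], Wo = yd[1], Cout = yd[2];
  const int K = kh * kw * C, L = Ho * Wo;

  arma::mat dWm(K, Cout, arma::fill::zeros);
  arma::rowvec db(Cout, arma::fill::zeros);
  arma::mat cols(K, L);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, kh, kw, stride, pad,
           Ho, Wo, cols);
    arma::mat dyt(const_cast<double*>(dy.begin()) + (size_t)L * Cout * n,
                  L, Cout, false, true);
    dWm += cols * dyt;
    db += arma::sum(dyt, 0);
  }
  NumericVector dw(dWm.begin(), dWm.end());
  dw.attr("dim") = IntegerVector::create(kh, kw, C, Cout);
  return List::create(_["dw"] = dw,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// Separable depthwise convolution (same 1-D kernel along rows then columns),
// used for the SSIM Gaussian window. pad = 0 gives a 'valid' result,
// pad = length(k)-1 a 'full' one (backward pass of the valid case with the
// kernel reversed by the caller).
// [[Rcpp::export(name = ".cpp_dwconv_sep")]]
NumericVector cpp_dwconv_sep(NumericVector x, NumericVector k, int pad) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int m = k.size();
  const int Hh = H + 2 * pad - m + 1;
  const int Wo = W + 2 * pad - m + 1;
  if (Hh < 1 || Wo < 1) stop("dwconv: kernel larger than padded input");

  // pass 1: along H
  std::vector<double> t((size_t)Hh * W * C * N, 0.0);
  for (size_t cn = 0; cn < (size_t)C * N; ++cn)
    for (int w = 0; w < W; ++w) {
      const double* col = x.begin() + (size_t)H * (w + W * cn);
      double* out = t.data() + (size_t)Hh * (w + W * cn);
      for (int o = 0; o < Hh; ++o) {
        double s = 0.0;
        for (int d = 0; d < m; ++d) {
          const int h = o + d - pad;
          if (h >= 0 && h < H) s += k[d] * col[h];
        }
        out[o] = s;
      }
    }
  // pass 2: along W
  NumericVector y((size_t)Hh * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Hh, Wo, C, N);
  for (size_t cn = 0; cn < (size_t)C * N; ++cn)
    for (int o = 0; o < Wo; ++o) {
      double* out = y.begin() + (size_t)Hh * (o + Wo * cn);
      for (int d = 0; d < m; ++d) {
        const int w = o + d - pad;
        if (w < 0 || w >= W) continue;
        const double* col = t.data() + (size_t)Hh * (w + W * cn);
        const double kd = k[d];
        for (int h = 0; h < Hh; ++h) out[h] += kd * col[h];
      }
    }
  return y;
}
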