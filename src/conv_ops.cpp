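// Low-level convolution / pooling kernels for the network layers.
// Array convention throughout: images are column-major R arrays with
// dim (H, W, C, N); convolution weights have dim (kh, kw, Cin, Cout).
// "Convolution" here is cross-correlation (no kernel flip), zero padding.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_size(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// Build the im2col matrix (K x Ho*Wo) for one sample.
// Row index r = ki + kh*(kj + kw*ci); column index c = ho + Ho*wo.
static void im2col(const double* x, int H, int W, int Cin,
                   int kh, int kw, int stride, int pad,
                   int Ho, int Wo, arma::mat& Xcol) {
  const size_t K = Xcol.n_rows;
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      double* dst = Xcol.memptr() + K * ((size_t)Ho * wo + ho);
      int ih0 = ho * stride - pad, iw0 = wo * stride - pad;
      for (int ci = 0; ci < Cin; ++ci) {
        const double* xc = x + (size_t)ci * H * W;
        for (int kj = 0; kj < kw; ++kj) {
          int iw = iw0 + kj;
          if (iw < 0 || iw >= W) {
            for (int ki = 0; ki < kh; ++ki) *dst++ = 0.0;
          } else {
            const double* col = xc + (size_t)iw * H;
            for (int ki = 0; ki < kh; ++ki) {
              int ih = ih0 + ki;
              *dst++ = (ih < 0 || ih >= H) ? 0.0 : col[ih];
            }
          }
        }
      }
    }
  }
}

// Scatter-add the columns of dXcol back into dx (col2im adjoint).
static void col2im(const arma::mat& dXcol, int H, int W, int Cin,
                   int kh, int kw, int stride, int pad,
                   int Ho, int Wo, double* dx) {
  const size_t K = dXcol.n_rows;
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const double* src = dXcol.memptr() + K * ((size_t)Ho * wo + ho);
      int ih0 = ho * stride - pad, iw0 = wo * stride - pad;
      for (int ci = 0; ci < Cin; ++ci) {
        double* xc = dx + (size_t)ci * H * W;
        for (int kj = 0; kj < kw; ++kj) {
          int iw = iw0 + kj;
          if (iw < 0 || iw >= W) { src += kh; continue; }
          double* col = xc + (size_t)iw * H;
          for (int ki = 0; ki < kh; ++ki) {
            int ih = ih0 + ki;
            if (ih >= 0 && ih < H) col[ih] += *src;
            ++src;
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w,
                             NumericVector b, int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cout = wd[3];
  if (wd[2] != Cin) stop("conv2d: weight Cin mismatch");
  int Ho = out_size(H, kh, stride, pad), Wo = out_size(W, kw, stride, pad);
  if (Ho <= 0 || Wo <= 0) stop("conv2d: output size non-positive");
  int K = kh * kw * Cin;
  arma::mat Wmat(const_cast<double*>(w.begin()), K, Cout, false, true);
  NumericVector y((size_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat Xcol(K, (size_t)Ho * Wo);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * Cin, H, W, Cin, kh, kw, stride, pad, Ho, Wo, Xcol);
    arma::mat Ymat(y.begin() + (size_t)n * Ho * Wo * Cout, (size_t)Ho * Wo, Cout, false, true);
    Ymat = Xcol.t() * Wmat;
    for (int co = 0; co < Cout; ++co) Ymat.col(co) += b[co];
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_bwd_data(NumericVector dy, NumericVector w,
                                  int stride, int pad, int H, int W) {
  IntegerVector yd = dy.attr("dim"), wd = w.attr("dim");
  int Ho = yd[0], Wo = yd[1], Cout = yd[2], N = yd[3];
  int kh = wd[0], kw = wd[1], Cin = wd[2];
  if (wd[3] != Cout) stop("conv2d_bwd_data: weight Cout mismatch");
  int K = kh * kw * Cin;
  arma::mat Wmat(const_cast<double*>(w.begin()), K, Cout, false, true);
  NumericVector dx((size_t)H * W * Cin * N);
  dx.attr("dim") = IntegerVector::create(H, W, Cin, N);
  for (int n = 0; n < N; ++n) {
    arma::mat dYmat(const_cast<double*>(dy.begin()) + (size_t)n * Ho * Wo * Cout,
                    (size_t)Ho * Wo, Cout, false, true);
    arma::mat dXcol = Wmat * dYmat.t();
    col2im(dXcol, H, W, Cin, kh, kw, stride, pad, Ho, Wo,
           dx.begin() + (size_t)n * H * W * Cin);
  }
  return dx;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd_param(NumericVector x, NumericVector dy,
                          int kh, int kw, int stride, int pad) {
  IntegerVector xd = x.attr("dim"), yd = dy.attr("dim");
  int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  int Ho = yd[0], Wo = yd[1], Cout = yd[2];
  int K = kh * kw * Cin;
  arma::mat dW(K, Cout, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  arma::mat Xcol(K, (size_t)Ho * Wo);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * Cin, H, W, Cin, kh, kw, stride, pad, Ho, Wo, Xcol);
    arma::mat dYmat(const_cast<double*>(dy.begin()) + (size_t)n * Ho * Wo * Cout,
                    (size_t)Ho * Wo, Cout, false, true);
    dW += Xcol * dYmat;
    db += arma::sum(dYmat, 0).t();
  }
  NumericVector dWout(dW.begin(), dW.end());
  dWout.attr("dim") = IntegerVector::create(kh, kw, Cin, Cout);
  return List::create(_["dw"] = dWout, _["db"] = NumericVector(db.begin(), db.end()));
}

// 2x2 max pooling with stride 2; ties resolved to the first element in
// column-major window order so the backward routing is exclusive.
// [[Rcpp::export]]
List cpp_maxpool2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * N);
  IntegerVector idx((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  size_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + ((size_t)n * C + c) * H * W;
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          size_t base = (size_t)(2 * wo) * H + 2 * ho;
          size_t cand[4] = {base, base + 1, base + H, base + H + 1};
          int best = 0;
          for (int k = 1; k < 4; ++k) if (xc[cand[k]] > xc[cand[best]]) best = k;
          // column-major output offset: ho + Ho*wo within channel plane
          size_t oo = ((size_t)n * C + c) * Ho * Wo + (size_t)wo * Ho + ho;
          y[oo] = xc[cand[best]];
          idx[oo] = (int)cand[best];
          ++o;
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bwd(NumericVector dy, IntegerVector idx, int H, int W) {
  IntegerVector yd = dy.attr("dim");
  int Ho = yd[0], Wo = yd[1], C = yd[2], N = yd[3];
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double* dxc = dx.begin() + ((size_t)n * C + c) * H * W;
      const double* dyc = dy.begin() + ((size_t)n * C + c) * Ho * Wo;
      const int* ic = idx.begin() + ((size_t)n * C + c) * Ho * Wo;
      for (size_t j = 0; j < (size_t)Ho * Wo; ++j) dxc[ic[j]] += dyc[j];
    }
  return dx;
}
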