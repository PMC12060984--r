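#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// 2-D convolution primitives used by the residual quality network.
// Array layout follows R column-major conventions throughout:
//   activations: (H, W, C, N), kernels: (k, k, Cin, Cout).
// im2col row ordering is ki + k*kj + k*k*ci, which is exactly the natural
// flattening of an R (k, k, Cin) array, so kernel matrices need no reshuffle.

static void im2col(const double* x, int H, int W, int C,
                   int k, int stride, int pad, int Ho, int Wo,
                   arma::mat& cols) {
  const int KK = k * k;
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const int colIdx = ho + Ho * wo;
      double* dst = cols.colptr(colIdx);
      const int h0 = ho * stride - pad;
      const int w0 = wo * stride - pad;
      for (int c = 0; c < C; ++c) {
        const double* xc = x + (std::size_t)H * W * c;
        for (int kj = 0; kj < k; ++kj) {
          const int w = w0 + kj;
          if (w < 0 || w >= W) {
            for (int ki = 0; ki < k; ++ki) dst[c * KK + kj * k + ki] = 0.0;
            continue;
          }
          const double* xcw = xc + (std::size_t)H * w;
          for (int ki = 0; ki < k; ++ki) {
            const int h = h0 + ki;
            dst[c * KK + kj * k + ki] = (h < 0 || h >= H) ? 0.0 : xcw[h];
          }
        }
      }
    }
  }
}

static void col2im(const arma::mat& cols, int H, int W, int C,
                   int k, int stride, int pad, int Ho, int Wo,
                   double* dx) {
  const int KK = k * k;
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const int colIdx = ho + Ho * wo;
      const double* src = cols.colptr(colIdx);
      const int h0 = ho * stride - pad;
      const int w0 = wo * stride - pad;
      for (int c = 0; c < C; ++c) {
        double* xc = dx + (std::size_t)H * W * c;
        for (int kj = 0; kj < k; ++kj) {
          const int w = w0 + kj;
          if (w < 0 || w >= W) continue;
          double* xcw = xc + (std::size_t)H * w;
          for (int ki = 0; ki < k; ++ki) {
            const int h = h0 + ki;
            if (h >= 0 && h < H) xcw[h] += src[c * KK + kj * k + ki];
          }
        }
      }
    }
  }
}

static inline int outExtent(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// [[Rcpp::export(name = ".conv2dForward")]]
NumericVector conv2dForward(NumericVector x, NumericVector w, NumericVector b,
                            int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("channel mismatch between input and kernel");
  const int Ho = outExtent(H, k, stride, pad), Wo = outExtent(W, k, stride, pad);

  NumericVector out(Rcpp::no_init((R_xlen_t)Ho * Wo * Cout * N));
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);

  arma::mat Wm(w.begin(), (std::size_t)k * k * Cin, Cout, false, true);
  arma::mat cols((std::size_t)k * k * Cin, (std::size_t)Ho * Wo);
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (std::size_t)H * W * C * n;
    im2col(xn, H, W, C, k, stride, pad, Ho, Wo, cols);
    arma::mat on(out.begin() + (std::size_t)Ho * Wo * Cout * n,
                 (std::size_t)Ho * Wo, Cout, false, true);
    on = cols.t() * Wm;
    for (int co = 0; co < Cout; ++co) on.col(co) += b[co];
  }
  return out;
}

// [[Rcpp::export(name = ".conv2dBackward")]]
List conv2dBackward(NumericVector x, NumericVector w, NumericVector dout,
                    int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[3];
  const int Ho = outExtent(H, k, stride, pad), Wo = outExtent(W, k, stride, pad);

  NumericVector dx((R_xlen_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  NumericVector dw((R_xlen_t)k * k * C * Cout);
  dw.attr("dim") = wd;
  NumericVector db(Cout);

  arma::mat Wm(w.begin(), (std::size_t)k * k * C, Cout, false, true);
  arma::mat dWm(dw.begin(), (std::size_t)k * k * C, Cout, false, true);
  arma::vec dbv(db.begin(), Cout, false, true);
  arma::mat cols((std::size_t)k * k * C, (std::size_t)Ho * Wo);

  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (std::size_t)H * W * C * n;
    im2col(xn, H, W, C, k, stride, pad, Ho, Wo, cols);
    arma::mat dn(const_cast<double*>(dout.begin()) + (std::size_t)Ho * Wo * Cout * n,
                 (std::size_t)Ho * Wo, Cout, false, true);
    dWm += cols * dn;
    dbv += arma::sum(dn, 0).t();
    arma::mat dcols = Wm * dn.t();
    col2im(dcols, H, W, C, k, stride, pad, Ho, Wo,
           dx.begin() + (std::size_t)H * W * C * n);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}
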