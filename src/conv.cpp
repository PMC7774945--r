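// Batched 2D convolution layers (same zero padding, odd square kernels) used
// by the residual-learning super-resolution network. Implemented as
// im2col + GEMM so mini-batch training stays CPU-friendly.
//
// Array layouts follow R column-major order:
//   x: [H, W, Cin, B]   w: [k, k, Cin, Cout]   y: [H, W, Cout, B]
// im2col column index = di + k*dj + k*k*ci, matching the flattened kernel.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

// Fill M (H*W x k*k*Cin) with padded shifts of one batch item.
void im2col(const double *x, int H, int W, int Cin, int k, arma::mat &M) {
  const int pad = k / 2;
  M.zeros();
  for (int ci = 0; ci < Cin; ++ci) {
    const double *xc = x + (size_t)H * W * ci;
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int col = di + k * dj + k * k * ci;
        const int oi = di - pad, oj = dj - pad;
        // output position (h, w) reads x(h + oi, w + oj)
        const int h0 = std::max(0, -oi), h1 = std::min(H, H - oi);
        const int w0 = std::max(0, -oj), w1 = std::min(W, W - oj);
        double *dst = M.colptr(col);
        for (int w = w0; w < w1; ++w) {
          const double *src = xc + (size_t)(w + oj) * H + oi;
          double *d = dst + (size_t)w * H;
          for (int h = h0; h < h1; ++h) d[h] = src[h];
        }
      }
    }
  }
}

// Scatter-add columns of M (H*W x k*k*Cin) back into gx for one batch item.
void col2im_add(const arma::mat &M, int H, int W, int Cin, int k, double *gx) {
  const int pad = k / 2;
  for (int ci = 0; ci < Cin; ++ci) {
    double *xc = gx + (size_t)H * W * ci;
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int col = di + k * dj + k * k * ci;
        const int oi = di - pad, oj = dj - pad;
        const int h0 = std::max(0, -oi), h1 = std::min(H, H - oi);
        const int w0 = std::max(0, -oj), w1 = std::min(W, W - oj);
        const double *src = M.colptr(col);
        for (int w = w0; w < w1; ++w) {
          double *dst = xc + (size_t)(w + oj) * H + oi;
          const double *s = src + (size_t)w * H;
          for (int h = h0; h < h1; ++h) dst[h] += s[h];
        }
      }
    }
  }
}

}  // namespace

// [[Rcpp::export]]
NumericVector cpp_conv_forward(NumericVector x, IntegerVector xdim,
                               NumericVector w, IntegerVector wdim,
                               NumericVector bias) {
  const int H = xdim[0], W = xdim[1], Cin = xdim[2], B = xdim[3];
  const int k = wdim[0], Cout = wdim[3];
  arma::mat Wm(const_cast<double *>(w.begin()), (size_t)k * k * Cin, Cout,
               false, true);
  NumericVector y((R_xlen_t)H * W * Cout * B);
  arma::mat M((size_t)H * W, (size_t)k * k * Cin);
  for (int n = 0; n < B; ++n) {
    im2col(x.begin() + (size_t)H * W * Cin * n, H, W, Cin, k, M);
    arma::mat Y = M * Wm;
    Y.each_row() += arma::rowvec(const_cast<double *>(bias.begin()), Cout,
                                 false, true);
    std::copy(Y.begin(), Y.end(), y.begin() + (size_t)H * W * Cout * n);
  }
  y.attr("dim") = IntegerVector::create(H, W, Cout, B);
  return y;
}

// [[Rcpp::export]]
List cpp_conv_backward(NumericVector x, IntegerVector xdim, NumericVector w,
                       IntegerVector wdim, NumericVector gy) {
  const int H = xdim[0], W = xdim[1], Cin = xdim[2], B = xdim[3];
  const int k = wdim[0], Cout = wdim[3];
  arma::mat Wm(const_cast<double *>(w.begin()), (size_t)k * k * Cin, Cout,
               false, true);
  NumericVector gx((R_xlen_t)H * W * Cin * B);
  arma::mat GW((size_t)k * k * Cin, Cout, arma::fill::zeros);
  arma::rowvec GB(Cout, arma::fill::zeros);
  arma::mat M((size_t)H * W, (size_t)k * k * Cin);
  for (int n = 0; n < B; ++n) {
    arma::mat Gy(const_cast<double *>(gy.begin()) + (size_t)H * W * Cout * n,
                 (size_t)H * W, Cout, false, true);
    im2col(x.begin() + (size_t)H * W * Cin * n, H, W, Cin, k, M);
    GW += M.t() * Gy;
    GB += arma::sum(Gy, 0);
    arma::mat Gcol = Gy * Wm.t();  // H*W x k*k*Cin
    col2im_add(Gcol, H, W, Cin, k, gx.begin() + (size_t)H * W * Cin * n);
  }
  gx.attr("dim") = IntegerVector::create(H, W, Cin, B);
  NumericVector gwv(GW.begin(), GW.end());
  gwv.attr("dim") = wdim;
  return List::create(_["gx"] = gx, _["gw"] = gwv,
                      _["gb"] = NumericVector(GB.begin(), GB.end()));
}
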