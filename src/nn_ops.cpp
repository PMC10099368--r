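// Low-level numeric kernels for the detector's feature-map operations.
// Layout convention: a feature map is an H x W x C cube (R array dim c(H, W, C));
// a conv weight arrives flattened as a (k*k*Cin) x Cout matrix whose row index
// is i + k*j + k*k*c for kernel offset (i, j) and input channel c, matching the
// natural flattening of an R array dim c(k, k, Cin, Cout).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::mat im2col(const arma::cube& x, int k, int stride, int pad,
                        int& Ho, int& Wo) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  Ho = (H + 2 * pad - k) / stride + 1;
  Wo = (W + 2 * pad - k) / stride + 1;
  arma::mat col(k * k * C, (size_t)Ho * Wo, arma::fill::zeros);
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const size_t cidx = (size_t)wo * Ho + ho;  // ho fastest
      const int h0 = ho * stride - pad, w0 = wo * stride - pad;
      for (int c = 0; c < C; ++c) {
        for (int j = 0; j < k; ++j) {
          const int w = w0 + j;
          if (w < 0 || w >= W) continue;
          for (int i = 0; i < k; ++i) {
            const int h = h0 + i;
            if (h < 0 || h >= H) continue;
            col(c * k * k + j * k + i, cidx) = x(h, w, c);
          }
        }
      }
    }
  }
  return col;
}

// [[Rcpp::export]]
arma::cube cpp_conv2d_fwd(const arma::cube& x, const arma::mat& w,
                          const arma::vec& bias, int k, int stride, int pad) {
  int Ho, Wo;
  arma::mat col = im2col(x, k, stride, pad, Ho, Wo);
  arma::mat out = w.t() * col;  // Cout x (Ho*Wo)
  if (bias.n_elem == out.n_rows) out.each_col() += bias;
  arma::cube y(Ho, Wo, out.n_rows);
  for (size_t c = 0; c < out.n_rows; ++c) {
    y.slice(c) = arma::reshape(out.row(c), Ho, Wo);
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(const arma::cube& x, const arma::mat& w,
                    const arma::cube& dout, int k, int stride, int pad,
                    bool has_bias) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  int Ho, Wo;
  arma::mat col = im2col(x, k, stride, pad, Ho, Wo);
  const int Cout = dout.n_slices;
  arma::mat dout_m(Cout, (size_t)Ho * Wo);
  for (int c = 0; c < Cout; ++c) {
    dout_m.row(c) = arma::vectorise(dout.slice(c)).t();
  }
  arma::mat dw = col * dout_m.t();            // (k*k*C) x Cout
  arma::mat dcol = w * dout_m;                // (k*k*C) x (Ho*Wo)
  arma::cube dx(H, W, C, arma::fill::zeros);  // col2im scatter-add
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const size_t cidx = (size_t)wo * Ho + ho;
      const int h0 = ho * stride - pad, w0 = wo * stride - pad;
      for (int c = 0; c < C; ++c) {
        for (int j = 0; j < k; ++j) {
          const int wp = w0 + j;
          if (wp < 0 || wp >= W) continue;
          for (int i = 0; i < k; ++i) {
            const int hp = h0 + i;
            if (hp < 0 || hp >= H) continue;
            dx(hp, wp, c) += dcol(c * k * k + j * k + i, cidx);
          }
        }
      }
    }
  }
  List res = List::create(_["dx"] = dx, _["dw"] = dw);
  if (has_bias) res["db"] = arma::vec(arma::sum(dout_m, 1));
  return res;
}

// Max pooling with "same"-style zero-free padding: padded positions are -Inf
// so they never win. Returns argmax as 0-based linear index into each H*W slice.
// [[Rcpp::export]]
List cpp_maxpool_fwd(const arma::cube& x, int k, int stride, int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  arma::cube y(Ho, Wo, C);
  arma::icube idx(Ho, Wo, C);
  for (int c = 0; c < C; ++c) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const int h0 = ho * stride - pad, w0 = wo * stride - pad;
        double best = -arma::datum::inf;
        long long bidx = -1;
        for (int j = 0; j < k; ++j) {
          const int w = w0 + j;
          if (w < 0 || w >= W) continue;
          for (int i = 0; i < k; ++i) {
            const int h = h0 + i;
            if (h < 0 || h >= H) continue;
            const double v = x(h, w, c);
            if (v > best) { best = v; bidx = (long long)w * H + h; }
          }
        }
        y(ho, wo, c) = best;
        idx(ho, wo, c) = bidx;
      }
    }
  }
  return List::create(_["out"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool_bwd(const arma::icube& idx, const arma::cube& dout,
                           int H, int W) {
  const int C = dout.n_slices;
  arma::cube dx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const long long n = (long long)dout.n_rows * dout.n_cols;
    for (long long t = 0; t < n; ++t) {
      const long long at = idx.slice(c)(t);
      if (at >= 0) dx.slice(c)(at) += dout.slice(c)(t);
    }
  }
  return dx;
}
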