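// Fused forward/backward kernels for one conv / transposed-conv block:
// pre-activation, convolution (im2col + GEMM), bias, instance norm, and
// post-activation in a single call. Layout conventions match imops.cpp:
// feature maps are (H*W) x C with pixel p = row + col*H. Per-block
// activations are cached in native objects handed to R as external
// pointers, so nothing but block inputs/outputs crosses the R boundary.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_dim_conv(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}
static inline int out_dim_convt(int n, int k, int stride, int pad) {
  return (n - 1) * stride - 2 * pad + k;
}

static arma::mat im2col_a(const arma::mat& x, int H, int W, int C,
                          int k, int stride, int pad) {
  const int Ho = out_dim_conv(H, k, stride, pad);
  const int Wo = out_dim_conv(W, k, stride, pad);
  arma::mat out(k * k * C, Ho * Wo, arma::fill::zeros);
  for (int jo = 0; jo < Wo; ++jo)
    for (int io = 0; io < Ho; ++io) {
      const int q = io + jo * Ho;
      for (int c = 0; c < C; ++c)
        for (int dj = 0; dj < k; ++dj) {
          const int j = jo * stride - pad + dj;
          if (j < 0 || j >= W) continue;
          for (int di = 0; di < k; ++di) {
            const int i = io * stride - pad + di;
            if (i < 0 || i >= H) continue;
            out(di + k * dj + k * k * c, q) = x(i + j * H, c);
          }
        }
    }
  return out;
}

static arma::mat col2im_a(const arma::mat& cols, int H, int W, int C,
                          int k, int stride, int pad) {
  const int Ho = out_dim_conv(H, k, stride, pad);
  const int Wo = out_dim_conv(W, k, stride, pad);
  arma::mat out(H * W, C, arma::fill::zeros);
  for (int jo = 0; jo < Wo; ++jo)
    for (int io = 0; io < Ho; ++io) {
      const int q = io + jo * Ho;
      for (int c = 0; c < C; ++c)
        for (int dj = 0; dj < k; ++dj) {
          const int j = jo * stride - pad + dj;
          if (j < 0 || j >= W) continue;
          for (int di = 0; di < k; ++di) {
            const int i = io * stride - pad + di;
            if (i < 0 || i >= H) continue;
            out(i + j * H, c) += cols(di + k * dj + k * k * c, q);
          }
        }
    }
  return out;
}

// activations: 0 none, 1 lrelu(0.2), 2 relu, 3 tanh
static arma::mat apply_act(const arma::mat& x, int act) {
  if (act == 0) return x;
  arma::mat y = x;
  if (act == 1) y.for_each([](double& v) { if (v < 0) v *= 0.2; });
  else if (act == 2) y.for_each([](double& v) { if (v < 0) v = 0; });
  else y = arma::tanh(y);
  return y;
}

// gradient through an activation given its *output* (valid for lrelu/relu,
// whose output sign matches the input sign, and for tanh).
static void act_grad_inplace(arma::mat& dy, const arma::mat& y_out, int act) {
  if (act == 0) return;
  if (act == 1) {
    for (arma::uword i = 0; i < dy.n_elem; ++i)
      if (y_out[i] < 0) dy[i] *= 0.2;
  } else if (act == 2) {
    for (arma::uword i = 0; i < dy.n_elem; ++i)
      if (y_out[i] <= 0) dy[i] = 0;
  } else {
    dy %= (1.0 - arma::square(y_out));
  }
}

struct BlockCache {
  arma::mat a, cols, out;
  arma::mat xhat;
  arma::rowvec sd;
  int H_in, W_in, H_out, W_out;
};

// kind: 0 conv, 1 transposed conv (weights (k*k*out_ch) x in_ch).
// [[Rcpp::export]]
List cpp_block_fw(const arma::mat& x, int H, int W, int in_ch, int out_ch,
                  int k, int stride, int pad, int kind,
                  const arma::mat& Wm, const arma::vec& b,
                  bool norm, const arma::vec& gamma, const arma::vec& beta,
                  int pre_act, int post_act) {
  XPtr<BlockCache> cache(new BlockCache(), true);
  cache->a = apply_act(x, pre_act);
  arma::mat y;
  int Ho, Wo;
  if (kind == 0) {
    Ho = out_dim_conv(H, k, stride, pad);
    Wo = out_dim_conv(W, k, stride, pad);
    cache->cols = im2col_a(cache->a, H, W, in_ch, k, stride, pad);
    y = cache->cols.t() * Wm;
  } else {
    Ho = out_dim_convt(H, k, stride, pad);
    Wo = out_dim_convt(W, k, stride, pad);
    y = col2im_a(Wm * cache->a.t(), Ho, Wo, out_ch, k, stride, pad);
  }
  y.each_row() += b.t();
  if (norm) {
    arma::rowvec mu = arma::mean(y, 0);
    y.each_row() -= mu;
    cache->sd = arma::sqrt(arma::mean(arma::square(y), 0) + 1e-5);
    y.each_row() /= cache->sd;
    cache->xhat = y;
    y.each_row() %= gamma.t();
    y.each_row() += beta.t();
  }
  cache->out = apply_act(y, post_act);
  cache->H_in = H; cache->W_in = W; cache->H_out = Ho; cache->W_out = Wo;
  return List::create(_["out"] = cache->out, _["H"] = Ho, _["W"] = Wo,
                      _["cache"] = cache);
}

// [[Rcpp::export]]
List cpp_block_bw(arma::mat dy, int in_ch, int out_ch, int k, int stride,
                  int pad, int kind, const arma::mat& Wm,
                  bool norm, const arma::vec& gamma,
                  int pre_act, int post_act, SEXP cache_ptr) {
  XPtr<BlockCache> cache(cache_ptr);
  act_grad_inplace(dy, cache->out, post_act);
  arma::vec dgamma, dbeta;
  if (norm) {
    dgamma = arma::sum(dy % cache->xhat, 0).t();
    dbeta = arma::sum(dy, 0).t();
    dy.each_row() %= gamma.t();
    arma::rowvec m1 = arma::mean(dy, 0);
    arma::rowvec m2 = arma::mean(dy % cache->xhat, 0);
    arma::mat xm2 = cache->xhat;
    xm2.each_row() %= m2;
    dy.each_row() -= m1;
    dy -= xm2;
    dy.each_row() /= cache->sd;
  }
  arma::vec db = arma::sum(dy, 0).t();
  arma::mat dW, dx;
  if (kind == 0) {
    dW = cache->cols * dy;
    dx = col2im_a(Wm * dy.t(), cache->H_in, cache->W_in, in_ch,
                  k, stride, pad);
  } else {
    arma::mat dy_cols = im2col_a(dy, cache->H_out, cache->W_out, out_ch,
                                 k, stride, pad);
    dW = dy_cols * cache->a;
    dx = dy_cols.t() * Wm;
  }
  act_grad_inplace(dx, cache->a, pre_act);
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db,
                      _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// Elementwise gradient accumulation: acc += g, in place.
// [[Rcpp::export]]
void cpp_axpy(NumericVector acc, const NumericVector& g) {
  const R_xlen_t n = acc.size();
  if (g.size() != n) stop("axpy: length mismatch");
  for (R_xlen_t i = 0; i < n; ++i) acc[i] += g[i];
}
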