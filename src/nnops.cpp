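// Low-level numeric kernels for the 2D U-Net.
// Tensor layout everywhere: R arrays dim (H, W, C, N), column-major, double.
// Convolutions are 'same' (zero padding), stride 1; weights are stored as a
// (k*k*Cin) x F matrix with patch-row index  j = dy + k*(dx + k*c).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline void get_dims4(const NumericVector& x, int& H, int& W, int& C, int& N) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4D (H, W, C, N) array");
  H = d[0]; W = d[1]; C = d[2]; N = d[3];
}

// Gather one sample into patch matrix P: (H*W) x (k*k*C).
static void im2col(const double* x, int H, int W, int C, int k, int pad,
                   arma::mat& P) {
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)H * W * c;
    for (int dx = 0; dx < k; ++dx) {
      for (int dy = 0; dy < k; ++dy) {
        int j = dy + k * (dx + k * c);
        double* col = P.colptr(j);
        int h_lo = std::max(0, pad - dy), h_hi = std::min(H, H + pad - dy);
        for (int w = 0; w < W; ++w) {
          int ws = w + dx - pad;
          double* cw = col + (size_t)H * w;
          if (ws < 0 || ws >= W) { std::fill(cw, cw + H, 0.0); continue; }
          if (h_lo > 0) std::fill(cw, cw + h_lo, 0.0);
          if (h_hi > h_lo)
            std::memcpy(cw + h_lo, xc + (h_lo + dy - pad) + (size_t)H * ws,
                        (h_hi - h_lo) * sizeof(double));
          if (h_hi < H) std::fill(cw + h_hi, cw + H, 0.0);
        }
      }
    }
  }
}

// Scatter-add transpose of im2col.
static void col2im(const arma::mat& P, int H, int W, int C, int k, int pad,
                   double* gx) {
  for (int c = 0; c < C; ++c) {
    double* gc = gx + (size_t)H * W * c;
    for (int dx = 0; dx < k; ++dx) {
      for (int dy = 0; dy < k; ++dy) {
        int j = dy + k * (dx + k * c);
        const double* col = P.colptr(j);
        int h_lo = std::max(0, pad - dy), h_hi = std::min(H, H + pad - dy);
        for (int w = 0; w < W; ++w) {
          int ws = w + dx - pad;
          if (ws < 0 || ws >= W) continue;
          const double* cw = col + (size_t)H * w;
          double* gw_ = gc + (h_lo + dy - pad) + (size_t)H * ws;
          for (int h = h_lo; h < h_hi; ++h) gw_[h - h_lo] += cw[h];
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericMatrix wgt,
                             NumericVector bias, int k) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  int pad = (k - 1) / 2;
  if (wgt.nrow() != k * k * C) stop("weight rows do not match k*k*Cin");
  int F = wgt.ncol();
  NumericVector y((size_t)H * W * F * N);
  y.attr("dim") = IntegerVector::create(H, W, F, N);
  arma::mat Wm(wgt.begin(), wgt.nrow(), F, false);
  arma::rowvec b(bias.begin(), F);
  arma::mat P(H * W, k * k * C);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, k, pad, P);
    arma::mat Y(y.begin() + (size_t)H * W * F * n, H * W, F, false, true);
    Y = P * Wm;
    Y.each_row() += b;
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericMatrix wgt, NumericVector gy, int k) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  int pad = (k - 1) / 2;
  int F = wgt.ncol();
  arma::mat Wm(wgt.begin(), wgt.nrow(), F, false);
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  arma::mat gW(k * k * C, F, arma::fill::zeros);
  arma::rowvec gb(F, arma::fill::zeros);
  arma::mat P(H * W, k * k * C);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, k, pad, P);
    arma::mat Gy(gy.begin() + (size_t)H * W * F * n, H * W, F, false);
    gW += P.t() * Gy;
    gb += arma::sum(Gy, 0);
    arma::mat Gp = Gy * Wm.t();
    col2im(Gp, H, W, C, k, pad, gx.begin() + (size_t)H * W * C * n);
  }
  return List::create(_["gx"] = gx,
                      _["gw"] = wrap(gW),
                      _["gb"] = wrap(arma::vec(gb.t())));
}

// 2x2 max pooling, stride 2. Returns pooled values and the linear argmax
// index (1-based, within the full input array) used by the backward pass.
// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector x) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  if (H % 2 || W % 2) stop("maxpool needs even spatial dims");
  int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * N);
  IntegerVector idx((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double* xp = x.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      size_t off = (size_t)H * W * (c + (size_t)C * n);
      size_t offo = (size_t)Ho * Wo * (c + (size_t)C * n);
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h) {
          size_t best = off + (2 * h) + (size_t)H * (2 * w);
          double bv = xp[best];
          size_t cand[3] = { off + (2 * h + 1) + (size_t)H * (2 * w),
                             off + (2 * h) + (size_t)H * (2 * w + 1),
                             off + (2 * h + 1) + (size_t)H * (2 * w + 1) };
          for (int t = 0; t < 3; ++t)
            if (xp[cand[t]] > bv) { bv = xp[cand[t]]; best = cand[t]; }
          y[offo + h + (size_t)Ho * w] = bv;
          idx[offo + h + (size_t)Ho * w] = (int)(best + 1);
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(IntegerVector idx, NumericVector gy,
                              IntegerVector in_dim) {
  size_t n = (size_t)in_dim[0] * in_dim[1] * in_dim[2] * in_dim[3];
  NumericVector gx(n);
  gx.attr("dim") = in_dim;
  for (R_xlen_t i = 0; i < gy.size(); ++i) gx[idx[i] - 1] += gy[i];
  return gx;
}

// 2x2 stride-2 transposed convolution ("up-convolution").
// Weight: (Cin) x (4*F) matrix, column index  j = a + 2*b + 4*f  where (a, b)
// is the (row, col) offset inside the 2x2 output block.
// [[Rcpp::export]]
NumericVector cpp_upconv_fwd(NumericVector x, NumericMatrix wgt, NumericVector bias) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  if (wgt.nrow() != C) stop("weight rows do not match Cin");
  int F = wgt.ncol() / 4;
  int Ho = 2 * H, Wo = 2 * W;
  NumericVector y((size_t)Ho * Wo * F * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, F, N);
  arma::mat Wm(wgt.begin(), C, 4 * F, false);
  for (int n = 0; n < N; ++n) {
    arma::mat X(const_cast<double*>(x.begin()) + (size_t)H * W * C * n,
                H * W, C, false);
    arma::mat Ym = X * Wm;  // (H*W) x (4F)
    double* yp = y.begin() + (size_t)Ho * Wo * F * n;
    for (int f = 0; f < F; ++f) {
      double bf = bias[f];
      for (int b = 0; b < 2; ++b)
        for (int a = 0; a < 2; ++a) {
          const double* col = Ym.colptr(a + 2 * b + 4 * f);
          double* yf = yp + (size_t)Ho * Wo * f;
          for (int w = 0; w < W; ++w)
            for (int h = 0; h < H; ++h)
              yf[(2 * h + a) + (size_t)Ho * (2 * w + b)] = col[h + H * w] + bf;
        }
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_upconv_bwd(NumericVector x, NumericMatrix wgt, NumericVector gy) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  int F = wgt.ncol() / 4;
  int Ho = 2 * H, Wo = 2 * W;
  arma::mat Wm(wgt.begin(), C, 4 * F, false);
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  arma::mat gW(C, 4 * F, arma::fill::zeros);
  arma::vec gb(F, arma::fill::zeros);
  arma::mat Gg(H * W, 4 * F);
  for (int n = 0; n < N; ++n) {
    const double* gp = gy.begin() + (size_t)Ho * Wo * F * n;
    for (int f = 0; f < F; ++f)
      for (int b = 0; b < 2; ++b)
        for (int a = 0; a < 2; ++a) {
          double* col = Gg.colptr(a + 2 * b + 4 * f);
          const double* gf = gp + (size_t)Ho * Wo * f;
          for (int w = 0; w < W; ++w)
            for (int h = 0; h < H; ++h)
              col[h + H * w] = gf[(2 * h + a) + (size_t)Ho * (2 * w + b)];
        }
    arma::mat X(const_cast<double*>(x.begin()) + (size_t)H * W * C * n,
                H * W, C, false);
    arma::mat Gx(gx.begin() + (size_t)H * W * C * n, H * W, C, false, true);
    Gx = Gg * Wm.t();
    gW += X.t() * Gg;
    for (int f = 0; f < F; ++f)
      gb[f] += arma::accu(Gg.cols(4 * f, 4 * f + 3));
  }
  return List::create(_["gx"] = gx, _["gw"] = wrap(gW), _["gb"] = wrap(gb));
}

// Batch normalization over (H, W, N) per channel; batch statistics.
// [[Rcpp::export]]
List cpp_bn_fwd(NumericVector x, NumericVector gamma, NumericVector beta,
                double eps) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  size_t hw = (size_t)H * W;
  NumericVector y(x.size()), xhat(x.size());
  y.attr("dim") = x.attr("dim");
  xhat.attr("dim") = x.attr("dim");
  NumericVector invstd(C);
  double n_eff = (double)hw * N;
  for (int c = 0; c < C; ++c) {
    double s = 0, s2 = 0;
    for (int n = 0; n < N; ++n) {
      const double* xc = x.begin() + hw * (c + (size_t)C * n);
      for (size_t i = 0; i < hw; ++i) { s += xc[i]; s2 += xc[i] * xc[i]; }
    }
    double mu = s / n_eff;
    double var = s2 / n_eff - mu * mu;
    if (var < 0) var = 0;
    double is = 1.0 / std::sqrt(var + eps);
    invstd[c] = is;
    double g = gamma[c], b = beta[c];
    for (int n = 0; n < N; ++n) {
      size_t off = hw * (c + (size_t)C * n);
      const double* xc = x.begin() + off;
      double* xh = xhat.begin() + off;
      double* yc = y.begin() + off;
      for (size_t i = 0; i < hw; ++i) {
        xh[i] = (xc[i] - mu) * is;
        yc[i] = g * xh[i] + b;
      }
    }
  }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["invstd"] = invstd);
}

// [[Rcpp::export]]
List cpp_bn_bwd(NumericVector gy, NumericVector xhat, NumericVector invstd,
                NumericVector gamma) {
  int H, W, C, N; get_dims4(gy, H, W, C, N);
  size_t hw = (size_t)H * W;
  NumericVector gx(gy.size());
  gx.attr("dim") = gy.attr("dim");
  NumericVector dgamma(C), dbeta(C);
  double n_eff = (double)hw * N;
  for (int c = 0; c < C; ++c) {
    double sg = 0, sgx = 0;
    for (int n = 0; n < N; ++n) {
      size_t off = hw * (c + (size_t)C * n);
      const double* g = gy.begin() + off;
      const double* xh = xhat.begin() + off;
      for (size_t i = 0; i < hw; ++i) { sg += g[i]; sgx += g[i] * xh[i]; }
    }
    dgamma[c] = sgx; dbeta[c] = sg;
    double gam = gamma[c], is = invstd[c];
    double sum_dxhat = sg * gam, sum_dxhat_xh = sgx * gam;
    for (int n = 0; n < N; ++n) {
      size_t off = hw * (c + (size_t)C * n);
      const double* g = gy.begin() + off;
      const double* xh = xhat.begin() + off;
      double* gxo = gx.begin() + off;
      for (size_t i = 0; i < hw; ++i) {
        double dxhat = g[i] * gam;
        gxo[i] = (is / n_eff) * (n_eff * dxhat - sum_dxhat - xh[i] * sum_dxhat_xh);
      }
    }
  }
  return List::create(_["gx"] = gx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// Per-pixel softmax over the class axis of an (H, W, K, N) array.
// [[Rcpp::export]]
NumericVector cpp_softmax(NumericVector logits) {
  int H, W, K, N; get_dims4(logits, H, W, K, N);
  size_t hw = (size_t)H * W;
  NumericVector p(logits.size());
  p.attr("dim") = logits.attr("dim");
  std::vector<double> buf(K);
  for (int n = 0; n < N; ++n) {
    size_t base = hw * (size_t)K * n;
    for (size_t i = 0; i < hw; ++i) {
      double m = R_NegInf;
      for (int k = 0; k < K; ++k) {
        buf[k] = logits[base + i + hw * k];
        if (buf[k] > m) m = buf[k];
      }
      double s = 0;
      for (int k = 0; k < K; ++k) { buf[k] = std::exp(buf[k] - m); s += buf[k]; }
      for (int k = 0; k < K; ++k) p[base + i + hw * k] = buf[k] / s;
    }
  }
  return p;
}
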