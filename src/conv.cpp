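// Batched 2-D convolution and max-pooling via im2col + GEMM.
// Tensor layout throughout: column-major R arrays dim = (H, W, C, N).
// Weight layout: matrix F x (k*k*Cin); column index enumerates
// (kh fastest, then kw, then input channel), matching im2col below.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline void get_dims(const NumericVector& x, int& H, int& W, int& C, int& N) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a rank-4 array (H, W, C, N)");
  H = d[0]; W = d[1]; C = d[2]; N = d[3];
}

// Fill one image's im2col block: cols is (k*k*C) x (Ho*Wo*N), this image's
// columns start at col0. Output position index p = wo*Ho + ho (column-major
// over the output map, matching R array order).
static void im2col_one(const double* x, int H, int W, int C,
                       int k, int stride, int pad, int Ho, int Wo,
                       arma::mat& cols, size_t col0) {
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      size_t cidx = col0 + (size_t)wo * Ho + ho;
      double* dst = cols.colptr(cidx);
      int h0 = ho * stride - pad, w0 = wo * stride - pad;
      size_t r = 0;
      for (int c = 0; c < C; ++c) {
        const double* xc = x + (size_t)c * H * W;
        for (int kw = 0; kw < k; ++kw) {
          int wi = w0 + kw;
          if (wi < 0 || wi >= W) {
            for (int kh = 0; kh < k; ++kh) dst[r++] = 0.0;
          } else {
            const double* xcw = xc + (size_t)wi * H;
            for (int kh = 0; kh < k; ++kh) {
              int hi = h0 + kh;
              dst[r++] = (hi < 0 || hi >= H) ? 0.0 : xcw[hi];
            }
          }
        }
      }
    }
  }
}

// Scatter-add one image's columns back into the input gradient.
static void col2im_one(const arma::mat& cols, size_t col0,
                       int H, int W, int C, int k, int stride, int pad,
                       int Ho, int Wo, double* dx) {
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      size_t cidx = col0 + (size_t)wo * Ho + ho;
      const double* src = cols.colptr(cidx);
      int h0 = ho * stride - pad, w0 = wo * stride - pad;
      size_t r = 0;
      for (int c = 0; c < C; ++c) {
        double* xc = dx + (size_t)c * H * W;
        for (int kw = 0; kw < k; ++kw) {
          int wi = w0 + kw;
          if (wi < 0 || wi >= W) { r += k; continue; }
          double* xcw = xc + (size_t)wi * H;
          for (int kh = 0; kh < k; ++kh) {
            int hi = h0 + kh;
            if (hi >= 0 && hi < H) xcw[hi] += src[r];
            ++r;
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd_cpp(NumericVector x, NumericMatrix w, NumericVector bias,
                             int stride, int pad) {
  int H, W, C, N; get_dims(x, H, W, C, N);
  int F = w.nrow(), k = (int)std::lround(std::sqrt((double)w.ncol() / C));
  if (k * k * C != w.ncol()) stop("weight columns != k*k*Cin");
  int Ho = (H + 2 * pad - k) / stride + 1, Wo = (W + 2 * pad - k) / stride + 1;
  if (Ho < 1 || Wo < 1) stop("spatial input too small for this kernel/stride");
  arma::mat cols(w.ncol(), (size_t)Ho * Wo * N);
  for (int n = 0; n < N; ++n)
    im2col_one(x.begin() + (size_t)n * H * W * C, H, W, C, k, stride, pad,
               Ho, Wo, cols, (size_t)n * Ho * Wo);
  arma::mat Wm(w.begin(), F, w.ncol(), false);
  arma::mat Y = Wm * cols;                       // F x (Ho*Wo*N)
  NumericVector out((size_t)Ho * Wo * F * N);
  double* po = out.begin();
  bool has_b = bias.size() == F;
  for (int n = 0; n < N; ++n)
    for (int f = 0; f < F; ++f) {
      double b = has_b ? bias[f] : 0.0;
      const size_t base = (size_t)n * Ho * Wo;
      double* dst = po + ((size_t)n * F + f) * Ho * Wo;
      for (size_t p = 0; p < (size_t)Ho * Wo; ++p) dst[p] = Y(f, base + p) + b;
    }
  out.attr("dim") = IntegerVector::create(Ho, Wo, F, N);
  return out;
}

// [[Rcpp::export]]
List conv2d_bwd_cpp(NumericVector x, NumericMatrix w, NumericVector dy,
                    int stride, int pad, bool has_bias) {
  int H, W, C, N; get_dims(x, H, W, C, N);
  int F = w.nrow(), k = (int)std::lround(std::sqrt((double)w.ncol() / C));
  int Ho = (H + 2 * pad - k) / stride + 1, Wo = (W + 2 * pad - k) / stride + 1;
  // repack dy (Ho,Wo,F,N) into F x (Ho*Wo*N)
  arma::mat dY(F, (size_t)Ho * Wo * N);
  const double* pd = dy.begin();
  for (int n = 0; n < N; ++n)
    for (int f = 0; f < F; ++f) {
      const double* src = pd + ((size_t)n * F + f) * Ho * Wo;
      const size_t base = (size_t)n * Ho * Wo;
      for (size_t p = 0; p < (size_t)Ho * Wo; ++p) dY(f, base + p) = src[p];
    }
  arma::mat cols(w.ncol(), (size_t)Ho * Wo * N);
  for (int n = 0; n < N; ++n)
    im2col_one(x.begin() + (size_t)n * H * W * C, H, W, C, k, stride, pad,
               Ho, Wo, cols, (size_t)n * Ho * Wo);
  arma::mat dW = dY * cols.t();                  // F x k*k*C
  arma::mat Wm(w.begin(), F, w.ncol(), false);
  arma::mat dcols = Wm.t() * dY;                 // k*k*C x Ho*Wo*N
  NumericVector dx((size_t)H * W * C * N);       // zero-initialised
  for (int n = 0; n < N; ++n)
    col2im_one(dcols, (size_t)n * Ho * Wo, H, W, C, k, stride, pad, Ho, Wo,
               dx.begin() + (size_t)n * H * W * C);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  NumericMatrix dWr(F, w.ncol());
  std::copy(dW.begin(), dW.end(), dWr.begin());
  List out = List::create(_["dx"] = dx, _["dw"] = dWr);
  if (has_bias) {
    NumericVector db(F);
    for (int f = 0; f < F; ++f) db[f] = arma::accu(dY.row(f));
    out["db"] = db;
  }
  return out;
}

// [[Rcpp::export]]
List maxpool_fwd_cpp(NumericVector x, int k, int stride, int pad) {
  int H, W, C, N; get_dims(x, H, W, C, N);
  int Ho = (H + 2 * pad - k) / stride + 1, Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector y((size_t)Ho * Wo * C * N);
  IntegerVector idx((size_t)Ho * Wo * C * N);    // 0-based argmax into the input plane
  const double* px = x.begin();
  double* py = y.begin(); int* pi = idx.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* plane = px + ((size_t)n * C + c) * H * W;
      size_t obase = ((size_t)n * C + c) * Ho * Wo;
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double best = -std::numeric_limits<double>::infinity(); int bi = -1;
          int h0 = ho * stride - pad, w0 = wo * stride - pad;
          for (int kw = 0; kw < k; ++kw) {
            int wi = w0 + kw; if (wi < 0 || wi >= W) continue;
            for (int kh = 0; kh < k; ++kh) {
              int hi = h0 + kh; if (hi < 0 || hi >= H) continue;
              double v = plane[(size_t)wi * H + hi];
              if (v > best) { best = v; bi = wi * H + hi; }
            }
          }
          size_t o = obase + (size_t)wo * Ho + ho;
          py[o] = best; pi[o] = bi;
        }
    }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  idx.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool_bwd_cpp(NumericVector dy, IntegerVector idx, IntegerVector xdim) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  IntegerVector d = dy.attr("dim");
  int Ho = d[0], Wo = d[1];
  NumericVector dx((size_t)H * W * C * N);
  const double* pd = dy.begin(); const int* pi = idx.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double* plane = dx.begin() + ((size_t)n * C + c) * H * W;
      size_t obase = ((size_t)n * C + c) * Ho * Wo;
      for (size_t p = 0; p < (size_t)Ho * Wo; ++p)
        plane[pi[obase + p]] += pd[obase + p];
    }
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  return dx;
}

// Batch normalisation over (H, W, N) per channel; layout (H, W, C, N).
// [[Rcpp::export]]
List bn_fwd_cpp(NumericVector x, NumericVector gamma, NumericVector beta,
                NumericVector rm, NumericVector rv, double eps,
                double momentum, bool training) {
  int H, W, C, N; get_dims(x, H, W, C, N);
  size_t HW = (size_t)H * W;
  NumericVector y(x.size()), xhat(x.size());
  NumericVector mu(C), sdv(C), rm2(clone(rm)), rv2(clone(rv));
  double m = (double)HW * N;
  for (int c = 0; c < C; ++c) {
    double s = 0.0, s2 = 0.0;
    if (training) {
      for (int n = 0; n < N; ++n) {
        const double* p = x.begin() + ((size_t)n * C + c) * HW;
        for (size_t i = 0; i < HW; ++i) { s += p[i]; s2 += p[i] * p[i]; }
      }
      double mean = s / m, var = s2 / m - mean * mean;
      if (var < 0) var = 0;
      mu[c] = mean;
      sdv[c] = std::sqrt(var + eps);
      double ub = (m > 1) ? var * m / (m - 1) : var;
      rm2[c] = (1 - momentum) * rm[c] + momentum * mean;
      rv2[c] = (1 - momentum) * rv[c] + momentum * ub;
    } else {
      mu[c] = rm[c];
      sdv[c] = std::sqrt(rv[c] + eps);
    }
    double g = gamma[c], b = beta[c], mean = mu[c], sd = sdv[c];
    for (int n = 0; n < N; ++n) {
      size_t off = ((size_t)n * C + c) * HW;
      const double* p = x.begin() + off;
      double* ph = xhat.begin() + off;
      double* py = y.begin() + off;
      for (size_t i = 0; i < HW; ++i) {
        ph[i] = (p[i] - mean) / sd;
        py[i] = g * ph[i] + b;
      }
    }
  }
  y.attr("dim") = x.attr("dim");
  xhat.attr("dim") = x.attr("dim");
  return List::create(_["y"] = y, _["xhat"] = xhat, _["sdv"] = sdv,
                      _["rm"] = rm2, _["rv"] = rv2);
}

// [[Rcpp::export]]
List bn_bwd_cpp(NumericVector dy, NumericVector xhat, NumericVector sdv,
                NumericVector gamma, bool training) {
  IntegerVector d = dy.attr("dim");
  int H = d[0], W = d[1], C = d[2], N = d[3];
  size_t HW = (size_t)H * W;
  double m = (double)HW * N;
  NumericVector dx(dy.size()), dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    double sg = 0.0, sb = 0.0;
    for (int n = 0; n < N; ++n) {
      size_t off = ((size_t)n * C + c) * HW;
      const double* pd = dy.begin() + off;
      const double* ph = xhat.begin() + off;
      for (size_t i = 0; i < HW; ++i) { sg += pd[i] * ph[i]; sb += pd[i]; }
    }
    dgamma[c] = sg; dbeta[c] = sb;
    double g = gamma[c], sd = sdv[c];
    double mean_dxhat = g * sb / m, mean_dxhat_xhat = g * sg / m;
    for (int n = 0; n < N; ++n) {
      size_t off = ((size_t)n * C + c) * HW;
      const double* pd = dy.begin() + off;
      const double* ph = xhat.begin() + off;
      double* px = dx.begin() + off;
      if (training)
        for (size_t i = 0; i < HW; ++i)
          px[i] = (g * pd[i] - mean_dxhat - ph[i] * mean_dxhat_xhat) / sd;
      else
        for (size_t i = 0; i < HW; ++i) px[i] = g * pd[i] / sd;
    }
  }
  dx.attr("dim") = dy.attr("dim");
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}
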