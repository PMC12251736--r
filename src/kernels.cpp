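// Dense tensor kernels for the detector engine.
//
// Feature maps are R double arrays with dim c(H, W, C, N) (column-major, so
// H varies fastest).  Convolution weights are arrays with dim
// c(k, k, Cin, Cout).  All kernels operate out-of-place and are exact; the
// backward passes are the adjoints of the forwards.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_size(int in, int k, int stride, int pad, int dil) {
  int keff = dil * (k - 1) + 1;
  return (in + 2 * pad - keff) / stride + 1;
}

// im2col for one sample: fills a (k*k*C) x (Ho*Wo) column block.
// Row index order: (kh, kw, c) with kh fastest; column order (ho, wo) with
// ho fastest — consistent with R's column-major array layout.
static void im2col_block(const double* x, int H, int W, int C,
                         int k, int stride, int pad, int dil,
                         int Ho, int Wo, double* out) {
  const int rows = k * k * C;
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      double* col = out + (wo * (size_t)Ho + ho) * rows;
      for (int c = 0; c < C; ++c) {
        const double* xc = x + (size_t)c * H * W;
        for (int kw = 0; kw < k; ++kw) {
          int w = wo * stride - pad + kw * dil;
          for (int kh = 0; kh < k; ++kh) {
            int h = ho * stride - pad + kh * dil;
            double v = 0.0;
            if (h >= 0 && h < H && w >= 0 && w < W)
              v = xc[(size_t)w * H + h];
            col[c * k * k + kw * k + kh] = v;
          }
        }
      }
    }
  }
}

// Adjoint of im2col_block: scatter-add columns back into the input grad.
static void col2im_block(const double* cols, int H, int W, int C,
                         int k, int stride, int pad, int dil,
                         int Ho, int Wo, double* dx) {
  const int rows = k * k * C;
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const double* col = cols + (wo * (size_t)Ho + ho) * rows;
      for (int c = 0; c < C; ++c) {
        double* xc = dx + (size_t)c * H * W;
        for (int kw = 0; kw < k; ++kw) {
          int w = wo * stride - pad + kw * dil;
          if (w < 0 || w >= W) continue;
          for (int kh = 0; kh < k; ++kh) {
            int h = ho * stride - pad + kh * dil;
            if (h < 0 || h >= H) continue;
            xc[(size_t)w * H + h] += col[c * k * k + kw * k + kh];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd_cpp(NumericVector x, NumericVector w,
                             int stride, int pad, int dil) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int k = wd[0], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d: channel mismatch (%d vs %d)", Cin, C);
  int Ho = out_size(H, k, stride, pad, dil);
  int Wo = out_size(W, k, stride, pad, dil);
  if (Ho <= 0 || Wo <= 0) stop("conv2d: output would be empty");

  // weight as (k*k*C) x Cout matrix (memory layout already matches)
  arma::mat Wm(const_cast<double*>(w.begin()), k * k * C, Cout, false, true);
  NumericVector y(Rcpp::no_init((R_xlen_t)Ho * Wo * Cout * N));
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat cols(k * k * C, (size_t)Ho * Wo);

  for (int n = 0; n < N; ++n) {
    im2col_block(x.begin() + (size_t)n * H * W * C, H, W, C,
                 k, stride, pad, dil, Ho, Wo, cols.memptr());
    // (Ho*Wo) x Cout block, column-major => exactly [Ho, Wo, Cout] layout
    arma::mat yb(y.begin() + (size_t)n * Ho * Wo * Cout,
                 (size_t)Ho * Wo, Cout, false, true);
    yb = cols.t() * Wm;
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bwd_cpp(NumericVector x, NumericVector w, NumericVector dy,
                    int stride, int pad, int dil, bool need_dx) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int k = wd[0], Cout = wd[3];
  int Ho = out_size(H, k, stride, pad, dil);
  int Wo = out_size(W, k, stride, pad, dil);

  arma::mat Wm(const_cast<double*>(w.begin()), k * k * C, Cout, false, true);
  arma::mat dW(k * k * C, Cout, arma::fill::zeros);
  NumericVector dx(need_dx ? (R_xlen_t)H * W * C * N : 0);
  if (need_dx) dx.attr("dim") = xd;
  arma::mat cols(k * k * C, (size_t)Ho * Wo);

  for (int n = 0; n < N; ++n) {
    im2col_block(x.begin() + (size_t)n * H * W * C, H, W, C,
                 k, stride, pad, dil, Ho, Wo, cols.memptr());
    arma::mat dyb(const_cast<double*>(dy.begin()) + (size_t)n * Ho * Wo * Cout,
                  (size_t)Ho * Wo, Cout, false, true);
    dW += cols * dyb;
    if (need_dx) {
      arma::mat dcols = Wm * dyb.t();  // (k*k*C) x (Ho*Wo)
      col2im_block(dcols.memptr(), H, W, C, k, stride, pad, dil, Ho, Wo,
                   dx.begin() + (size_t)n * H * W * C);
    }
  }
  NumericVector dWout(dW.begin(), dW.end());
  dWout.attr("dim") = wd;
  return List::create(_["dw"] = dWout, _["dx"] = dx);
}

// Max pooling, stride/pad general, dilation 1.  Returns pooled map and the
// 1-based linear argmax index into x (per output element) for the backward.
// [[Rcpp::export]]
List maxpool_fwd_cpp(NumericVector x, int k, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = out_size(H, k, stride, pad, 1);
  int Wo = out_size(W, k, stride, pad, 1);
  if (Ho <= 0 || Wo <= 0) stop("maxpool: output would be empty");

  NumericVector y(Rcpp::no_init((R_xlen_t)Ho * Wo * C * N));
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector arg(Rcpp::no_init((R_xlen_t)Ho * Wo * C * N));

  R_xlen_t o = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + ((size_t)n * C + c) * H * W;
      R_xlen_t base = ((size_t)n * C + c) * H * W;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double best = R_NegInf; R_xlen_t bi = -1;
          for (int kw = 0; kw < k; ++kw) {
            int w = wo * stride - pad + kw;
            if (w < 0 || w >= W) continue;
            for (int kh = 0; kh < k; ++kh) {
              int h = ho * stride - pad + kh;
              if (h < 0 || h >= H) continue;
              double v = xc[(size_t)w * H + h];
              if (v > best) { best = v; bi = base + (size_t)w * H + h; }
            }
          }
          // R arrays are [Ho, Wo, C, N]: index (ho, wo) maps to ho + Ho*wo
          R_xlen_t oi = o + (R_xlen_t)wo * Ho + ho;
          y[oi] = best;
          arg[oi] = (int)(bi + 1);
        }
      }
      o += (R_xlen_t)Ho * Wo;
    }
  }
  return List::create(_["y"] = y, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector maxpool_bwd_cpp(NumericVector dy, IntegerVector argmax,
                              IntegerVector xdim) {
  R_xlen_t nx = (R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector dx(nx);
  dx.attr("dim") = xdim;
  for (R_xlen_t i = 0; i < dy.size(); ++i)
    dx[argmax[i] - 1] += dy[i];
  return dx;
}

// Nearest-neighbour upsampling by integer factor f.
// [[Rcpp::export]]
NumericVector upsample_fwd_cpp(NumericVector x, int f) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = H * f, Wo = W * f;
  NumericVector y(Rcpp::no_init((R_xlen_t)Ho * Wo * C * N));
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (R_xlen_t cn = 0; cn < (R_xlen_t)C * N; ++cn) {
    const double* xs = x.begin() + cn * H * W;
    double* ys = y.begin() + cn * (R_xlen_t)Ho * Wo;
    for (int w = 0; w < Wo; ++w) {
      const double* xcol = xs + (size_t)(w / f) * H;
      double* ycol = ys + (size_t)w * Ho;
      for (int h = 0; h < Ho; ++h) ycol[h] = xcol[h / f];
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector upsample_bwd_cpp(NumericVector dy, int f) {
  IntegerVector yd = dy.attr("dim");
  int Ho = yd[0], Wo = yd[1], C = yd[2], N = yd[3];
  int H = Ho / f, W = Wo / f;
  NumericVector dx((R_xlen_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (R_xlen_t cn = 0; cn < (R_xlen_t)C * N; ++cn) {
    const double* ys = dy.begin() + cn * (R_xlen_t)Ho * Wo;
    double* xs = dx.begin() + cn * (R_xlen_t)H * W;
    for (int w = 0; w < Wo; ++w) {
      double* xcol = xs + (size_t)(w / f) * H;
      const double* ycol = ys + (size_t)w * Ho;
      for (int h = 0; h < Ho; ++h) xcol[h / f] += ycol[h];
    }
  }
  return dx;
}
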