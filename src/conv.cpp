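// Dense-array kernels for the detection network.
//
// Tensor layout throughout: column-major R arrays with dim (H, W, C, N),
// so each (channel, sample) plane of H*W values is contiguous. Convolution
// is im2col + one GEMM per (sample, group); depthwise convs are just
// groups == channels. Padding is explicit (top, bottom, left, right) so the
// asymmetric "same" padding of even strip kernels (k = 10) is exact.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline void get_dims4(const NumericVector &x, int &H, int &W, int &C, int &N) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d array (H, W, C, N)");
  H = d[0]; W = d[1]; C = d[2]; N = d[3];
}

// Fill the im2col matrix M (OH*OW rows, KH*KW*Cg cols) for one sample/group.
static void im2col(const double *xp, int H, int W, int c0, int Cg,
                   int KH, int KW, int stride, int pt, int pl,
                   int OH, int OW, arma::mat &M) {
  for (int cg = 0; cg < Cg; ++cg) {
    const double *plane = xp + (size_t)(c0 + cg) * H * W;
    for (int kw = 0; kw < KW; ++kw) {
      for (int kh = 0; kh < KH; ++kh) {
        double *col = M.colptr(kh + KH * (kw + KW * cg));
        for (int ow = 0; ow < OW; ++ow) {
          int iw = ow * stride - pl + kw;
          double *dst = col + (size_t)ow * OH;
          if (iw < 0 || iw >= W) {
            std::fill(dst, dst + OH, 0.0);
            continue;
          }
          const double *src = plane + (size_t)iw * H;
          for (int oh = 0; oh < OH; ++oh) {
            int ih = oh * stride - pt + kh;
            dst[oh] = (ih < 0 || ih >= H) ? 0.0 : src[ih];
          }
        }
      }
    }
  }
}

// Scatter-add of the column matrix back to the input gradient (col2im).
static void col2im_add(double *xp, int H, int W, int c0, int Cg,
                       int KH, int KW, int stride, int pt, int pl,
                       int OH, int OW, const arma::mat &M) {
  for (int cg = 0; cg < Cg; ++cg) {
    double *plane = xp + (size_t)(c0 + cg) * H * W;
    for (int kw = 0; kw < KW; ++kw) {
      for (int kh = 0; kh < KH; ++kh) {
        const double *col = M.colptr(kh + KH * (kw + KW * cg));
        for (int ow = 0; ow < OW; ++ow) {
          int iw = ow * stride - pl + kw;
          if (iw < 0 || iw >= W) continue;
          double *dst = plane + (size_t)iw * H;
          const double *src = col + (size_t)ow * OH;
          for (int oh = 0; oh < OH; ++oh) {
            int ih = oh * stride - pt + kh;
            if (ih >= 0 && ih < H) dst[ih] += src[oh];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".cw_conv2d_fwd")]]
NumericVector cw_conv2d_fwd(NumericVector x, NumericVector w,
                            Nullable<NumericVector> bias,
                            int stride, IntegerVector pad, int groups) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  IntegerVector wd = w.attr("dim");
  int KH = wd[0], KW = wd[1], Cg = wd[2], Cout = wd[3];
  if (Cg * groups != C) stop("weight/input channel mismatch");
  int Coutg = Cout / groups;
  int pt = pad[0], pb = pad[1], pl = pad[2], pr = pad[3];
  int OH = (H + pt + pb - KH) / stride + 1;
  int OW = (W + pl + pr - KW) / stride + 1;
  if (OH < 1 || OW < 1) stop("output size would be empty");

  NumericVector y((size_t)OH * OW * Cout * N);
  y.attr("dim") = IntegerVector::create(OH, OW, Cout, N);
  const double *xp0 = x.begin();
  double *yp0 = y.begin();
  int K = KH * KW * Cg;
  arma::mat M(OH * OW, K);
  for (int n = 0; n < N; ++n) {
    const double *xp = xp0 + (size_t)n * H * W * C;
    double *yp = yp0 + (size_t)n * OH * OW * Cout;
    for (int g = 0; g < groups; ++g) {
      im2col(xp, H, W, g * Cg, Cg, KH, KW, stride, pt, pl, OH, OW, M);
      const arma::mat Wg(const_cast<double *>(w.begin()) + (size_t)g * Coutg * K,
                         K, Coutg, false, true);
      arma::mat Yg(yp + (size_t)g * Coutg * OH * OW, OH * OW, Coutg, false, true);
      Yg = M * Wg;
    }
  }
  if (bias.isNotNull()) {
    NumericVector b(bias);
    for (int n = 0; n < N; ++n)
      for (int c = 0; c < Cout; ++c) {
        double *yp = yp0 + (size_t)(c + (size_t)n * Cout) * OH * OW;
        double bc = b[c];
        for (int i = 0; i < OH * OW; ++i) yp[i] += bc;
      }
  }
  return y;
}

// [[Rcpp::export(name = ".cw_conv2d_bwd")]]
List cw_conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy,
                   int stride, IntegerVector pad, int groups, bool need_dx,
                   bool has_bias) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  IntegerVector wd = w.attr("dim");
  int KH = wd[0], KW = wd[1], Cg = wd[2], Cout = wd[3];
  int Coutg = Cout / groups;
  int pt = pad[0], pl = pad[2];
  IntegerVector dyd = dy.attr("dim");
  int OH = dyd[0], OW = dyd[1];
  int K = KH * KW * Cg;

  NumericVector dw((size_t)KH * KW * Cg * Cout);
  dw.attr("dim") = wd;
  NumericVector dx;
  if (need_dx) {
    dx = NumericVector((size_t)H * W * C * N);
    dx.attr("dim") = IntegerVector::create(H, W, C, N);
  }
  NumericVector db(has_bias ? Cout : 0);

  const double *xp0 = x.begin();
  const double *dyp0 = dy.begin();
  arma::mat M(OH * OW, K), dM(OH * OW, K);
  for (int n = 0; n < N; ++n) {
    const double *xp = xp0 + (size_t)n * H * W * C;
    const double *dyp = dyp0 + (size_t)n * OH * OW * Cout;
    for (int g = 0; g < groups; ++g) {
      im2col(xp, H, W, g * Cg, Cg, KH, KW, stride, pt, pl, OH, OW, M);
      const arma::mat dYg(const_cast<double *>(dyp) + (size_t)g * Coutg * OH * OW,
                          OH * OW, Coutg, false, true);
      arma::mat dWg(dw.begin() + (size_t)g * Coutg * K, K, Coutg, false, true);
      dWg += M.t() * dYg;
      if (need_dx) {
        const arma::mat Wg(const_cast<double *>(w.begin()) + (size_t)g * Coutg * K,
                           K, Coutg, false, true);
        dM = dYg * Wg.t();
        col2im_add(dx.begin() + (size_t)n * H * W * C, H, W, g * Cg, Cg,
                   KH, KW, stride, pt, pl, OH, OW, dM);
      }
    }
    if (has_bias)
      for (int c = 0; c < Cout; ++c) {
        const double *p = dyp + (size_t)c * OH * OW;
        double s = 0; for (int i = 0; i < OH * OW; ++i) s += p[i];
        db[c] += s;
      }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Stride-1 k x k average pooling with symmetric (k-1)/2 padding (k odd),
// dividing by k*k always (zero-padded border included in the average).
// The operator is symmetric, so the backward pass is the same function
// applied to the output gradient.
// [[Rcpp::export(name = ".cw_avgpool_same")]]
NumericVector cw_avgpool_same(NumericVector x, int k) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  int p = (k - 1) / 2;
  double inv = 1.0 / (k * k);
  NumericVector y((size_t)H * W * C * N);
  y.attr("dim") = x.attr("dim");
  // separable: horizontal then vertical running windows per plane
  std::vector<double> tmp((size_t)H * W);
  for (size_t plane = 0; plane < (size_t)C * N; ++plane) {
    const double *xp = x.begin() + plane * H * W;
    double *yp = y.begin() + plane * H * W;
    // vertical pass: tmp(h, w) = sum over kh of x(h - p + kh, w)
    for (int w_ = 0; w_ < W; ++w_) {
      const double *col = xp + (size_t)w_ * H;
      double *t = tmp.data() + (size_t)w_ * H;
      for (int h = 0; h < H; ++h) {
        int lo = std::max(0, h - p), hi = std::min(H - 1, h + k - 1 - p);
        double s = 0; for (int i = lo; i <= hi; ++i) s += col[i];
        t[h] = s;
      }
    }
    // horizontal pass
    for (int h = 0; h < H; ++h) {
      for (int w_ = 0; w_ < W; ++w_) {
        int lo = std::max(0, w_ - p), hi = std::min(W - 1, w_ + k - 1 - p);
        double s = 0;
        for (int i = lo; i <= hi; ++i) s += tmp[(size_t)i * H + h];
        yp[(size_t)w_ * H + h] = s * inv;
      }
    }
  }
  return y;
}

// Per-channel mean and (biased) variance over (H, W, N).
// [[Rcpp::export(name = ".cw_channel_stats")]]
List cw_channel_stats(NumericVector x) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  size_t HW = (size_t)H * W;
  NumericVector mean(C), var(C);
  for (int c = 0; c < C; ++c) {
    double s = 0, s2 = 0;
    for (int n = 0; n < N; ++n) {
      const double *p = x.begin() + HW * (c + (size_t)n * C);
      for (size_t i = 0; i < HW; ++i) { s += p[i]; s2 += p[i] * p[i]; }
    }
    double m = s / (HW * N);
    mean[c] = m;
    var[c] = s2 / (HW * N) - m * m;
  }
  return List::create(_["mean"] = mean, _["var"] = var);
}

// y = x * scale[c] + shift[c]
// [[Rcpp::export(name = ".cw_channel_affine")]]
NumericVector cw_channel_affine(NumericVector x, NumericVector scale,
                                NumericVector shift) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  size_t HW = (size_t)H * W;
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double *p = x.begin() + HW * (c + (size_t)n * C);
      double *q = y.begin() + HW * (c + (size_t)n * C);
      double a = scale[c], b = shift[c];
      for (size_t i = 0; i < HW; ++i) q[i] = p[i] * a + b;
    }
  return y;
}

// per-channel sum of a * b over (H, W, N)
// [[Rcpp::export(name = ".cw_channel_dot")]]
NumericVector cw_channel_dot(NumericVector a, NumericVector b) {
  int H, W, C, N; get_dims4(a, H, W, C, N);
  size_t HW = (size_t)H * W;
  NumericVector out(C);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double *p = a.begin() + HW * (c + (size_t)n * C);
      const double *q = b.begin() + HW * (c + (size_t)n * C);
      double s = 0; for (size_t i = 0; i < HW; ++i) s += p[i] * q[i];
      out[c] += s;
    }
  return out;
}

// Batch-norm input gradient given normalized activations and channel sums.
// dx = g * invstd * (dy - mean(dy) - xhat * mean(dy * xhat)), means over (H,W,N).
// [[Rcpp::export(name = ".cw_bn_bwd")]]
NumericVector cw_bn_bwd(NumericVector dy, NumericVector xhat,
                        NumericVector gamma, NumericVector invstd,
                        NumericVector sum_dy, NumericVector sum_dy_xhat,
                        bool train_stats) {
  int H, W, C, N; get_dims4(dy, H, W, C, N);
  size_t HW = (size_t)H * W;
  double m = (double)HW * N;
  NumericVector dx(dy.size());
  dx.attr("dim") = dy.attr("dim");
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double *pd = dy.begin() + HW * (c + (size_t)n * C);
      const double *px = xhat.begin() + HW * (c + (size_t)n * C);
      double *q = dx.begin() + HW * (c + (size_t)n * C);
      double g = gamma[c] * invstd[c];
      double mdy = train_stats ? sum_dy[c] / m : 0.0;
      double mdyx = train_stats ? sum_dy_xhat[c] / m : 0.0;
      for (size_t i = 0; i < HW; ++i)
        q[i] = g * (pd[i] - mdy - px[i] * mdyx);
    }
  return dx;
}

// Nearest-neighbour 2x upsampling and its adjoint.
// [[Rcpp::export(name = ".cw_upsample2")]]
NumericVector cw_upsample2(NumericVector x) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  int OH = 2 * H, OW = 2 * W;
  NumericVector y((size_t)OH * OW * C * N);
  y.attr("dim") = IntegerVector::create(OH, OW, C, N);
  for (size_t plane = 0; plane < (size_t)C * N; ++plane) {
    const double *xp = x.begin() + plane * H * W;
    double *yp = y.begin() + plane * OH * OW;
    for (int w_ = 0; w_ < OW; ++w_) {
      const double *col = xp + (size_t)(w_ / 2) * H;
      double *dst = yp + (size_t)w_ * OH;
      for (int h = 0; h < OH; ++h) dst[h] = col[h / 2];
    }
  }
  return y;
}

// [[Rcpp::export(name = ".cw_upsample2_bwd")]]
NumericVector cw_upsample2_bwd(NumericVector dy) {
  int OH, OW, C, N; get_dims4(dy, OH, OW, C, N);
  int H = OH / 2, W = OW / 2;
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (size_t plane = 0; plane < (size_t)C * N; ++plane) {
    const double *yp = dy.begin() + plane * OH * OW;
    double *xp = dx.begin() + plane * H * W;
    for (int w_ = 0; w_ < OW; ++w_) {
      const double *src = yp + (size_t)w_ * OH;
      double *col = xp + (size_t)(w_ / 2) * H;
      for (int h = 0; h < OH; ++h) col[h / 2] += src[h];
    }
  }
  return dx;
}
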