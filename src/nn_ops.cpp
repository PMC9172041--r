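// Low-level numeric kernels for the residual classifier: batched 2-D
// convolution (im2col + BLAS gemm) with its backward pass, and a bilinear
// displacement-field warp used by the augmentation pipeline.
//
// Tensor layout throughout: column-major R arrays dim (H, W, C, B);
// kernels dim (kh, kw, C, F). Flattened kernel row index = ki + kh*kj +
// kh*kw*c, matching as.vector() of the R array.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline arma::mat im2col(const double* x, int H, int W, int C, int B,
                               int kh, int kw, int sh, int sw, int ph, int pw,
                               int oh, int ow) {
  arma::mat K(kh * kw * C, (size_t)oh * ow * B, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    const double* xb = x + (size_t)b * H * W * C;
    for (int oj = 0; oj < ow; ++oj) {
      for (int oi = 0; oi < oh; ++oi) {
        size_t col = (size_t)b * oh * ow + (size_t)oj * oh + oi;
        double* Kcol = K.colptr(col);
        int i0 = oi * sh - ph, j0 = oj * sw - pw;
        for (int c = 0; c < C; ++c) {
          const double* xc = xb + (size_t)c * H * W;
          for (int kj = 0; kj < kw; ++kj) {
            int j = j0 + kj;
            if (j < 0 || j >= W) continue;
            const double* xcol = xc + (size_t)j * H;
            double* Kdst = Kcol + (size_t)c * kh * kw + (size_t)kj * kh;
            for (int ki = 0; ki < kh; ++ki) {
              int i = i0 + ki;
              if (i >= 0 && i < H) Kdst[ki] = xcol[i];
            }
          }
        }
      }
    }
  }
  return K;
}

static inline void col2im(const arma::mat& K, double* dx, int H, int W, int C,
                          int B, int kh, int kw, int sh, int sw, int ph,
                          int pw, int oh, int ow) {
  for (int b = 0; b < B; ++b) {
    double* xb = dx + (size_t)b * H * W * C;
    for (int oj = 0; oj < ow; ++oj) {
      for (int oi = 0; oi < oh; ++oi) {
        size_t col = (size_t)b * oh * ow + (size_t)oj * oh + oi;
        const double* Kcol = K.colptr(col);
        int i0 = oi * sh - ph, j0 = oj * sw - pw;
        for (int c = 0; c < C; ++c) {
          double* xc = xb + (size_t)c * H * W;
          for (int kj = 0; kj < kw; ++kj) {
            int j = j0 + kj;
            if (j < 0 || j >= W) continue;
            double* xcol = xc + (size_t)j * H;
            const double* Ksrc = Kcol + (size_t)c * kh * kw + (size_t)kj * kh;
            for (int ki = 0; ki < kh; ++ki) {
              int i = i0 + ki;
              if (i >= 0 && i < H) xcol[i] += Ksrc[ki];
            }
          }
        }
      }
    }
  }
}

static void conv_dims(const IntegerVector& xd, const IntegerVector& wd,
                      const IntegerVector& stride, const IntegerVector& pad,
                      int& H, int& W, int& C, int& B, int& kh, int& kw,
                      int& F, int& oh, int& ow) {
  H = xd[0]; W = xd[1]; C = xd[2]; B = xd[3];
  kh = wd[0]; kw = wd[1]; F = wd[3];
  if (wd[2] != C) stop("kernel channel count does not match input");
  oh = (H + 2 * pad[0] - kh) / stride[0] + 1;
  ow = (W + 2 * pad[1] - kw) / stride[1] + 1;
  if (oh <= 0 || ow <= 0) stop("convolution output would be empty");
}

// Forward convolution. When `keep_cols` is true the im2col matrix is kept
// alive in an external pointer so the backward pass can reuse it without a
// copy.
// [[Rcpp::export(name = ".conv2d_forward")]]
SEXP conv2d_forward(NumericVector x, NumericVector w, NumericVector bias,
                    IntegerVector stride, IntegerVector pad,
                    bool keep_cols = false) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H, W, C, B, kh, kw, F, oh, ow;
  conv_dims(xd, wd, stride, pad, H, W, C, B, kh, kw, F, oh, ow);
  arma::mat* Kp = new arma::mat(im2col(x.begin(), H, W, C, B, kh, kw,
                                       stride[0], stride[1], pad[0], pad[1],
                                       oh, ow));
  arma::mat Wm(const_cast<double*>(w.begin()), kh * kw * C, F, false, true);
  arma::mat Yt = Kp->t() * Wm;  // (oh*ow*B) x F, gemm with transpose flag
  NumericVector out((size_t)oh * ow * F * B);
  out.attr("dim") = IntegerVector::create(oh, ow, F, B);
  double* o = out.begin();
  const double* bptr = bias.begin();
  size_t n = (size_t)oh * ow;
  for (int f = 0; f < F; ++f) {
    const double* src = Yt.colptr(f);
    for (int b = 0; b < B; ++b) {
      double* dst = o + ((size_t)b * F + f) * n;
      const double* s = src + (size_t)b * n;
      double bb = bptr[f];
      for (size_t p = 0; p < n; ++p) dst[p] = s[p] + bb;
    }
  }
  if (!keep_cols) { delete Kp; return out; }
  XPtr<arma::mat> xp(Kp, true);
  return List::create(_["y"] = out, _["cols"] = xp);
}

// Backward convolution; `cols` is the external pointer saved by the forward
// pass (the im2col matrix is recomputed when NULL).
// [[Rcpp::export(name = ".conv2d_backward")]]
List conv2d_backward(NumericVector x, NumericVector w, NumericVector dy,
                     IntegerVector stride, IntegerVector pad,
                     SEXP cols = R_NilValue) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H, W, C, B, kh, kw, F, oh, ow;
  conv_dims(xd, wd, stride, pad, H, W, C, B, kh, kw, F, oh, ow);
  // reorder dy (oh, ow, F, B) into DYt ((oh*ow*B) x F): contiguous copies
  arma::mat DYt((size_t)oh * ow * B, F);
  const double* d = dy.begin();
  size_t n = (size_t)oh * ow;
  for (int f = 0; f < F; ++f) {
    double* dst = DYt.colptr(f);
    for (int b = 0; b < B; ++b)
      std::memcpy(dst + (size_t)b * n, d + ((size_t)b * F + f) * n,
                  n * sizeof(double));
  }
  arma::mat dWm;
  if (cols != R_NilValue) {
    XPtr<arma::mat> Kp(cols);
    dWm = (*Kp) * DYt;
  } else {
    arma::mat K = im2col(x.begin(), H, W, C, B, kh, kw, stride[0], stride[1],
                         pad[0], pad[1], oh, ow);
    dWm = K * DYt;
  }
  arma::vec db = arma::sum(DYt, 0).t();
  arma::mat Wm(const_cast<double*>(w.begin()), kh * kw * C, F, false, true);
  arma::mat dK = Wm * DYt.t();           // (kh*kw*C) x (oh*ow*B)
  NumericVector dx((size_t)H * W * C * B);
  dx.attr("dim") = xd;
  col2im(dK, dx.begin(), H, W, C, B, kh, kw, stride[0], stride[1],
         pad[0], pad[1], oh, ow);
  NumericVector dwv(dWm.begin(), dWm.end());
  dwv.attr("dim") = wd;
  return List::create(_["dx"] = dx, _["dw"] = dwv,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// one-pass leaky ReLU and its input-side gradient
// [[Rcpp::export(name = ".lrelu")]]
NumericVector lrelu_cpp(NumericVector x, double slope) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const double* p = x.begin(); double* q = y.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i)
    q[i] = p[i] > 0 ? p[i] : slope * p[i];
  return y;
}

// [[Rcpp::export(name = ".lrelu_grad")]]
NumericVector lrelu_grad_cpp(NumericVector x, NumericVector dy,
                             double slope) {
  NumericVector g(x.size());
  g.attr("dim") = x.attr("dim");
  const double* p = x.begin(); const double* dp = dy.begin();
  double* q = g.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i)
    q[i] = p[i] > 0 ? dp[i] : slope * dp[i];
  return g;
}

// ---- batch normalization kernels (per channel over H, W, B) ------------

static inline void bn_dims(const IntegerVector& d, size_t& HW, int& C,
                           int& B) {
  HW = (size_t)d[0] * d[1]; C = d[2]; B = d[3];
}

// [[Rcpp::export(name = ".bn_stats")]]
List bn_stats(NumericVector x) {
  IntegerVector d = x.attr("dim");
  size_t HW; int C, B; bn_dims(d, HW, C, B);
  NumericVector mean(C), var(C);
  const double* xp = x.begin();
  for (int c = 0; c < C; ++c) {
    double s = 0, s2 = 0;
    for (int b = 0; b < B; ++b) {
      const double* p = xp + ((size_t)b * C + c) * HW;
      for (size_t i = 0; i < HW; ++i) { s += p[i]; s2 += p[i] * p[i]; }
    }
    double n = (double)HW * B;
    mean[c] = s / n;
    double v = s2 / n - mean[c] * mean[c];
    var[c] = v > 0 ? v : 0;
  }
  return List::create(_["mean"] = mean, _["var"] = var);
}

// y = x * a[channel] + b[channel]
// [[Rcpp::export(name = ".channel_affine")]]
NumericVector channel_affine(NumericVector x, NumericVector a,
                             NumericVector b) {
  IntegerVector d = x.attr("dim");
  size_t HW; int C, B; bn_dims(d, HW, C, B);
  NumericVector y(x.size());
  y.attr("dim") = d;
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int bb = 0; bb < B; ++bb)
    for (int c = 0; c < C; ++c) {
      const double* p = xp + ((size_t)bb * C + c) * HW;
      double* q = yp + ((size_t)bb * C + c) * HW;
      double ac = a[c], bc = b[c];
      for (size_t i = 0; i < HW; ++i) q[i] = p[i] * ac + bc;
    }
  return y;
}

// Batch-norm backward: given dy, xhat, gamma and the per-channel sd,
// returns dx, dgamma, dbeta in one pass.
// [[Rcpp::export(name = ".bn_backward")]]
List bn_backward_cpp(NumericVector dy, NumericVector xhat, NumericVector gamma,
                     NumericVector sd) {
  IntegerVector d = dy.attr("dim");
  size_t HW; int C, B; bn_dims(d, HW, C, B);
  NumericVector dgamma(C), dbeta(C);
  const double* dp = dy.begin();
  const double* hp = xhat.begin();
  for (int c = 0; c < C; ++c) {
    double s1 = 0, s2 = 0;
    for (int b = 0; b < B; ++b) {
      size_t off = ((size_t)b * C + c) * HW;
      const double* pd = dp + off;
      const double* ph = hp + off;
      for (size_t i = 0; i < HW; ++i) { s1 += pd[i]; s2 += pd[i] * ph[i]; }
    }
    dbeta[c] = s1; dgamma[c] = s2;
  }
  NumericVector dx(dy.size());
  dx.attr("dim") = d;
  double* xp = dx.begin();
  double n = (double)HW * B;
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      size_t off = ((size_t)b * C + c) * HW;
      const double* pd = dp + off;
      const double* ph = hp + off;
      double* px = xp + off;
      double m1 = dbeta[c] / n, m2 = dgamma[c] / n, g = gamma[c] / sd[c];
      for (size_t i = 0; i < HW; ++i)
        px[i] = (pd[i] - m1 - ph[i] * m2) * g;
    }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// Bilinear resampling of a single-channel image at fractional source
// coordinates (0-based): out[i, j] = img(mr[i, j], mc[i, j]); samples
// falling outside the image return `fill`.
// [[Rcpp::export(name = ".warp_bilinear")]]
NumericMatrix warp_bilinear(NumericMatrix img, NumericMatrix mr,
                            NumericMatrix mc, double fill) {
  int H = img.nrow(), W = img.ncol();
  int oh = mr.nrow(), ow = mr.ncol();
  NumericMatrix out(oh, ow);
  for (int j = 0; j < ow; ++j)
    for (int i = 0; i < oh; ++i) {
      double r = mr(i, j), c = mc(i, j);
      int r0 = (int)std::floor(r), c0 = (int)std::floor(c);
      double fr = r - r0, fc = c - c0;
      double acc = 0.0, wsum = 0.0;
      for (int dr = 0; dr <= 1; ++dr)
        for (int dc = 0; dc <= 1; ++dc) {
          int ri = r0 + dr, ci = c0 + dc;
          double wgt = (dr ? fr : 1 - fr) * (dc ? fc : 1 - fc);
          if (wgt == 0.0) continue;
          if (ri >= 0 && ri < H && ci >= 0 && ci < W) {
            acc += wgt * img(ri, ci);
            wsum += wgt;
          }
        }
      out(i, j) = acc + (1.0 - wsum) * fill;
    }
  return out;
}
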