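// Low-level tensor primitives for the Y-Net layers.
// All image tensors are R numeric arrays with dim (H, W, C, N), column-major,
// so the flat index of x[h, w, c, n] is h + H*(w + W*(c + C*n)).
// Convolution uses a transposed im2col (patch-major (N*P) x K matrix, filled
// with contiguous memcpy runs) followed by one BLAS GEMM for the whole
// batch; 1x1 convolutions skip im2col entirely.  Every forward has a
// matching exact backward, so reverse-mode gradients are analytic.

#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline IntegerVector tensor_dim(const NumericVector &x) {
  if (!x.hasAttribute("dim")) stop("expected an array with a dim attribute");
  return x.attr("dim");
}

static inline int out_size(int in, int k, int stride, int pad, int dil) {
  int eff = dil * (k - 1) + 1;
  return (in + 2 * pad - eff) / stride + 1;
}

// Fill column r = (i, j, c) of the patch-major matrix colsT ((N*P) x K) for
// all samples; rows are ordered p = oh + Ho*ow within sample, samples
// stacked.  acc = false writes (im2col), acc = true scatter-adds the
// column back into gx (col2im).
static void im2col_T(double *x, int H, int W, int Cin, int N,
                     int kh, int kw, int stride, int pad, int dil,
                     int Ho, int Wo, arma::mat &colsT, bool acc) {
  const size_t P = (size_t)Ho * Wo;
  const size_t samp = (size_t)H * W * Cin;
  for (int c = 0; c < Cin; ++c) {
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const int r = i + kh * (j + kw * c);
        double *col = colsT.colptr(r);
        const int hoff = i * dil - pad;   // h = oh*stride + hoff
        const int woff = j * dil - pad;   // w = ow*stride + woff
        // oh range with h in [0, H)
        int oh0 = hoff < 0 ? (-hoff + stride - 1) / stride : 0;
        int oh1 = (H - 1 - hoff) / stride;          // inclusive
        if (oh1 > Ho - 1) oh1 = Ho - 1;
        for (int n = 0; n < N; ++n) {
          double *plane = x + samp * n + (size_t)H * W * c;
          double *dst = col + P * n;
          for (int ow = 0; ow < Wo; ++ow, dst += Ho) {
            int w = ow * stride + woff;
            if (w < 0 || w >= W || oh0 > oh1) {
              if (!acc) std::memset(dst, 0, sizeof(double) * Ho);
              continue;
            }
            double *src = plane + (size_t)H * w;
            if (!acc) {
              if (oh0 > 0) std::memset(dst, 0, sizeof(double) * oh0);
              if (oh1 < Ho - 1)
                std::memset(dst + oh1 + 1, 0,
                            sizeof(double) * (Ho - 1 - oh1));
              if (stride == 1)
                std::memcpy(dst + oh0, src + oh0 + hoff,
                            sizeof(double) * (oh1 - oh0 + 1));
              else
                for (int oh = oh0; oh <= oh1; ++oh)
                  dst[oh] = src[oh * stride + hoff];
            } else {
              if (stride == 1) {
                double *s = src + oh0 + hoff;
                for (int oh = oh0; oh <= oh1; ++oh) s[oh - oh0] += dst[oh];
              } else {
                for (int oh = oh0; oh <= oh1; ++oh)
                  src[oh * stride + hoff] += dst[oh];
              }
            }
          }
        }
      }
    }
  }
}

// Restack y between the array layout (P x Cout blocks per sample) and the
// GEMM layout ((N*P) x Cout); direction: true = array -> stacked.
static void restack(double *arr, arma::mat &stk, int P, int Cout, int N,
                    bool to_stacked) {
  for (int n = 0; n < N; ++n)
    for (int o = 0; o < Cout; ++o) {
      double *a = arr + (size_t)P * o + (size_t)P * Cout * n;
      double *s = stk.colptr(o) + (size_t)P * n;
      if (to_stacked) std::memcpy(s, a, sizeof(double) * P);
      else std::memcpy(a, s, sizeof(double) * P);
    }
}

// Direct 3x3 stride-1 same-size convolution (pad == dil), used when the
// channel counts are too small for im2col+GEMM to pay off: the inner loop
// runs contiguously down image columns and auto-vectorizes.
static inline void shift_ranges(int off, int n, int &lo, int &hi) {
  lo = off < 0 ? -off : 0;        // first output index with a valid source
  hi = off > 0 ? n - off : n;     // one past the last valid output index
}

static void conv3_direct_fwd(const double *x, const double *w,
                             int H, int W, int Cin, int Cout, int N,
                             int dil, double *y) {
  const size_t HW = (size_t)H * W;
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      double *yp = y + HW * (co + (size_t)Cout * n);
      for (int ci = 0; ci < Cin; ++ci) {
        const double *xp = x + HW * (ci + (size_t)Cin * n);
        for (int j = 0; j < 3; ++j) {
          int woff = (j - 1) * dil, w0, w1;
          shift_ranges(woff, W, w0, w1);
          for (int i = 0; i < 3; ++i) {
            int hoff = (i - 1) * dil, h0, h1;
            shift_ranges(hoff, H, h0, h1);
            double wv = w[i + 3 * (j + 3 * (ci + Cin * co))];
            if (wv == 0) continue;
            for (int ow = w0; ow < w1; ++ow) {
              double *yc = yp + (size_t)H * ow + h0;
              const double *xc = xp + (size_t)H * (ow + woff) + h0 + hoff;
              int len = h1 - h0;
              for (int k = 0; k < len; ++k) yc[k] += wv * xc[k];
            }
          }
        }
      }
    }
}

static void conv3_direct_bwd(const double *x, const double *w,
                             const double *gy, int H, int W, int Cin,
                             int Cout, int N, int dil,
                             double *gx, double *gw) {
  const size_t HW = (size_t)H * W;
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      const double *gyp = gy + HW * (co + (size_t)Cout * n);
      for (int ci = 0; ci < Cin; ++ci) {
        const double *xp = x + HW * (ci + (size_t)Cin * n);
        double *gxp = gx ? gx + HW * (ci + (size_t)Cin * n) : nullptr;
        for (int j = 0; j < 3; ++j) {
          int woff = (j - 1) * dil, w0, w1;
          shift_ranges(woff, W, w0, w1);
          for (int i = 0; i < 3; ++i) {
            int hoff = (i - 1) * dil, h0, h1;
            shift_ranges(hoff, H, h0, h1);
            const int wi = i + 3 * (j + 3 * (ci + Cin * co));
            double wv = w[wi];
            double acc = 0;
            for (int ow = w0; ow < w1; ++ow) {
              const double *gc = gyp + (size_t)H * ow + h0;
              const double *xc = xp + (size_t)H * (ow + woff) + h0 + hoff;
              double *gxc = gxp ? gxp + (size_t)H * (ow + woff) + h0 + hoff
                                : nullptr;
              int len = h1 - h0;
              if (gxc)
                for (int k = 0; k < len; ++k) {
                  acc += xc[k] * gc[k];
                  gxc[k] += wv * gc[k];
                }
              else
                for (int k = 0; k < len; ++k) acc += xc[k] * gc[k];
            }
            gw[wi] += acc;
          }
        }
      }
    }
}

static inline bool use_direct3(int kh, int kw, int stride, int pad, int dil,
                               int Cin, int Cout) {
  return kh == 3 && kw == 3 && stride == 1 && pad == dil &&
    (Cin <= 8 || Cout <= 8);
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                         int stride, int pad, int dil) {
  IntegerVector xd = tensor_dim(x), wd = tensor_dim(w);
  int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cout = wd[3];
  if (wd[2] != Cin) stop("conv2d: weight input channels do not match input");
  int Ho = out_size(H, kh, stride, pad, dil);
  int Wo = out_size(W, kw, stride, pad, dil);
  if (Ho <= 0 || Wo <= 0) stop("conv2d: kernel larger than padded input");
  const int K = kh * kw * Cin;
  const size_t P = (size_t)Ho * Wo;

  NumericVector y(no_init(P * Cout * N));
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat wm(w.begin(), K, Cout, false, true);

  if (kh == 1 && kw == 1 && stride == 1 && pad == 0) {
    for (int n = 0; n < N; ++n) {
      arma::mat xn(x.begin() + (size_t)H * W * Cin * n, P, Cin, false, true);
      arma::mat yn(y.begin() + P * Cout * n, P, Cout, false, true);
      yn = xn * wm;
    }
  } else if (use_direct3(kh, kw, stride, pad, dil, Cin, Cout)) {
    std::memset(y.begin(), 0, sizeof(double) * y.size());
    conv3_direct_fwd(x.begin(), w.begin(), H, W, Cin, Cout, N, dil,
                     y.begin());
  } else {
    // scratch matrices are reused across calls to avoid repeated
    // multi-megabyte allocations (R runs this single-threaded)
    static arma::mat colsT, ys;
    colsT.set_size(P * N, K);
    im2col_T(x.begin(), H, W, Cin, N, kh, kw, stride, pad, dil,
             Ho, Wo, colsT, false);
    ys = colsT * wm;  // (N*P) x Cout
    restack(y.begin(), ys, (int)P, Cout, N, false);
  }
  if (b.size() > 0) {   // convolutions feeding batch-norm carry no bias
    for (int n = 0; n < N; ++n)
      for (int o = 0; o < Cout; ++o) {
        double *yo = y.begin() + P * o + P * Cout * n;
        double bo = b[o];
        for (size_t p = 0; p < P; ++p) yo[p] += bo;
      }
  }
  return y;
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector gy,
                int stride, int pad, int dil, bool need_gx, bool need_gb) {
  IntegerVector xd = tensor_dim(x), wd = tensor_dim(w), gd = tensor_dim(gy);
  int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cout = wd[3];
  int Ho = gd[0], Wo = gd[1];
  const int K = kh * kw * Cin;
  const size_t P = (size_t)Ho * Wo;

  arma::mat wm(w.begin(), K, Cout, false, true);
  NumericVector gwv(K * Cout);
  gwv.attr("dim") = wd;
  arma::mat gw(gwv.begin(), K, Cout, false, true);
  arma::vec gb(need_gb ? Cout : 0, arma::fill::zeros);
  if (need_gb)
    for (int n = 0; n < N; ++n) {
      arma::mat gyn(gy.begin() + P * Cout * n, P, Cout, false, true);
      gb += arma::sum(gyn, 0).t();
    }
  NumericVector gx;

  if (kh == 1 && kw == 1 && stride == 1 && pad == 0) {
    if (need_gx) {
      gx = NumericVector((size_t)H * W * Cin * N);
      gx.attr("dim") = xd;
    }
    for (int n = 0; n < N; ++n) {
      arma::mat xn(x.begin() + (size_t)H * W * Cin * n, P, Cin, false, true);
      arma::mat gyn(gy.begin() + P * Cout * n, P, Cout, false, true);
      gw += xn.t() * gyn;
      if (need_gx) {
        arma::mat gxn(gx.begin() + (size_t)H * W * Cin * n, P, Cin,
                      false, true);
        gxn = gyn * wm.t();
      }
    }
  } else if (use_direct3(kh, kw, stride, pad, dil, Cin, Cout)) {
    if (need_gx) {
      gx = NumericVector((size_t)H * W * Cin * N);
      gx.attr("dim") = xd;
    }
    conv3_direct_bwd(x.begin(), w.begin(), gy.begin(), H, W, Cin, Cout, N,
                     dil, need_gx ? gx.begin() : nullptr, gw.memptr());
  } else {
    static arma::mat gys, colsT, gcolsT;
    gys.set_size(P * N, Cout);
    restack(gy.begin(), gys, (int)P, Cout, N, true);
    colsT.set_size(P * N, K);
    im2col_T(x.begin(), H, W, Cin, N, kh, kw, stride, pad, dil,
             Ho, Wo, colsT, false);
    gw = colsT.t() * gys;
    if (need_gx) {
      gx = NumericVector((size_t)H * W * Cin * N);
      gx.attr("dim") = xd;
      gcolsT = gys * wm.t();  // (N*P) x K
      im2col_T(gx.begin(), H, W, Cin, N, kh, kw, stride, pad, dil,
               Ho, Wo, gcolsT, true);
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gwv,
                      _["gb"] = NumericVector(gb.begin(), gb.end()));
}

// ---- fused elementwise / per-channel kernels --------------------------------

// [[Rcpp::export(name = ".relu_fwd")]]
NumericVector relu_fwd(NumericVector x) {
  NumericVector y(no_init(x.size()));
  y.attr("dim") = x.attr("dim");
  const double *xi = x.begin();
  double *yi = y.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i) yi[i] = xi[i] > 0 ? xi[i] : 0;
  return y;
}

// [[Rcpp::export(name = ".relu_bwd")]]
NumericVector relu_bwd(NumericVector g, NumericVector y) {
  NumericVector gx(no_init(g.size()));
  gx.attr("dim") = g.attr("dim");
  const double *gi = g.begin(), *yi = y.begin();
  double *o = gx.begin();
  for (R_xlen_t i = 0; i < g.size(); ++i) o[i] = yi[i] > 0 ? gi[i] : 0;
  return gx;
}

// Per-channel sums of a and of a*b over (H, W, N), one pass.
// [[Rcpp::export(name = ".ch_sums2")]]
List ch_sums2(NumericVector a, NumericVector b) {
  IntegerVector xd = tensor_dim(a);
  int C = xd[2], N = xd[3];
  size_t HW = (size_t)xd[0] * xd[1];
  NumericVector sa(C), sab(C);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double *ai = a.begin() + HW * (c + (size_t)C * n);
      const double *bi = b.begin() + HW * (c + (size_t)C * n);
      double s1 = 0, s2 = 0;
      for (size_t p = 0; p < HW; ++p) { s1 += ai[p]; s2 += ai[p] * bi[p]; }
      sa[c] += s1; sab[c] += s2;
    }
  return List::create(_["sa"] = sa, _["sab"] = sab);
}

// Fused batch-norm (+ optional ReLU) forward: y = relu?(gamma*xhat + beta)
// with xhat = (x - mu)*istd, in a single pass.  xhat is not materialised;
// the backward recomputes it from x.
// [[Rcpp::export(name = ".bn_act_fwd")]]
NumericVector bn_act_fwd(NumericVector x, NumericVector gamma,
                         NumericVector beta, NumericVector mu,
                         NumericVector istd, bool relu) {
  IntegerVector xd = tensor_dim(x);
  int C = xd[2], N = xd[3];
  size_t HW = (size_t)xd[0] * xd[1];
  NumericVector y(no_init(x.size()));
  y.attr("dim") = xd;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double *xi = x.begin() + HW * (c + (size_t)C * n);
      double *yi = y.begin() + HW * (c + (size_t)C * n);
      double a = gamma[c] * istd[c], b = beta[c] - gamma[c] * istd[c] * mu[c];
      if (relu)
        for (size_t p = 0; p < HW; ++p) {
          double o = xi[p] * a + b;
          yi[p] = o > 0 ? o : 0;
        }
      else
        for (size_t p = 0; p < HW; ++p) yi[p] = xi[p] * a + b;
    }
  return y;
}

// Fused (ReLU +) batch-norm backward.  Pass 1 masks the upstream gradient
// by the ReLU activity (when y is given) and accumulates the per-channel
// sums; pass 2 forms the input gradient.  xhat is recomputed from x on the
// fly.  In eval mode (train = false) mean/variance are constants and the
// correction terms vanish.
// [[Rcpp::export(name = ".bn_act_bwd")]]
List bn_act_bwd(NumericVector g, NumericVector x, Nullable<NumericVector> y_,
                NumericVector gamma, NumericVector mu, NumericVector istd,
                bool train) {
  IntegerVector xd = tensor_dim(g);
  int C = xd[2], N = xd[3];
  size_t HW = (size_t)xd[0] * xd[1];
  double m = (double)HW * N;
  const bool relu = y_.isNotNull();
  NumericVector y;
  if (relu) y = y_.get();
  NumericVector gm(no_init(g.size()));
  gm.attr("dim") = xd;
  NumericVector dgamma(C), dbeta(C);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t off = HW * (c + (size_t)C * n);
      const double *gi = g.begin() + off;
      const double *xi = x.begin() + off;
      const double *yi = relu ? y.begin() + off : nullptr;
      double *o = gm.begin() + off;
      double mc = mu[c], is = istd[c];
      double s1 = 0, s2 = 0;
      for (size_t p = 0; p < HW; ++p) {
        double v = (!relu || yi[p] > 0) ? gi[p] : 0;
        o[p] = v;
        s1 += v;
        s2 += v * (xi[p] - mc) * is;
      }
      dbeta[c] += s1;
      dgamma[c] += s2;
    }
  NumericVector gx(no_init(g.size()));
  gx.attr("dim") = xd;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t off = HW * (c + (size_t)C * n);
      const double *gi = gm.begin() + off;
      const double *xi = x.begin() + off;
      double *o = gx.begin() + off;
      double ga = gamma[c], is = istd[c], mc = mu[c];
      double a1 = train ? ga * dbeta[c] / m : 0;
      double a2 = train ? ga * dgamma[c] / m : 0;
      for (size_t p = 0; p < HW; ++p)
        o[p] = (gi[p] * ga - a1 - (xi[p] - mc) * is * a2) * is;
    }
  return List::create(_["gx"] = gx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// Concatenate a list of (H, W, C_i, N) tensors along the channel axis.
// [[Rcpp::export(name = ".concat_c")]]
NumericVector concat_c(List xs) {
  int k = xs.size();
  std::vector<NumericVector> v(k);
  std::vector<int> ch(k);
  int Ctot = 0;
  IntegerVector d0;
  for (int i = 0; i < k; ++i) {
    v[i] = as<NumericVector>(xs[i]);
    IntegerVector d = tensor_dim(v[i]);
    if (i == 0) d0 = d;
    ch[i] = d[2];
    Ctot += d[2];
  }
  size_t HW = (size_t)d0[0] * d0[1];
  int N = d0[3];
  NumericVector y(no_init(HW * Ctot * N));
  y.attr("dim") = IntegerVector::create(d0[0], d0[1], Ctot, N);
  for (int n = 0; n < N; ++n) {
    double *dst = y.begin() + HW * (size_t)Ctot * n;
    for (int i = 0; i < k; ++i) {
      std::memcpy(dst, v[i].begin() + HW * (size_t)ch[i] * n,
                  sizeof(double) * HW * ch[i]);
      dst += HW * ch[i];
    }
  }
  return y;
}

// Slice channels [c0, c1) out of a (H, W, C, N) tensor (concat backward).
// [[Rcpp::export(name = ".slice_c")]]
NumericVector slice_c(NumericVector x, int c0, int c1) {
  IntegerVector d = tensor_dim(x);
  size_t HW = (size_t)d[0] * d[1];
  int C = d[2], N = d[3], Cs = c1 - c0;
  NumericVector y(no_init(HW * Cs * N));
  y.attr("dim") = IntegerVector::create(d[0], d[1], Cs, N);
  for (int n = 0; n < N; ++n)
    std::memcpy(y.begin() + HW * (size_t)Cs * n,
                x.begin() + HW * (c0 + (size_t)C * n),
                sizeof(double) * HW * Cs);
  return y;
}

// ---- resampling -------------------------------------------------------------

// Precompute 1-D bilinear sampling (half-pixel centers, clamped to edges).
static void bilin_axis(int in, int out, std::vector<int> &i0,
                       std::vector<int> &i1, std::vector<double> &w1) {
  i0.resize(out); i1.resize(out); w1.resize(out);
  double scale = (double)in / out;
  for (int o = 0; o < out; ++o) {
    double s = (o + 0.5) * scale - 0.5;
    if (s < 0) s = 0;
    if (s > in - 1) s = in - 1;
    int lo = (int)std::floor(s);
    int hi = std::min(lo + 1, in - 1);
    i0[o] = lo; i1[o] = hi; w1[o] = s - lo;
  }
}

// [[Rcpp::export(name = ".bilinear_fwd")]]
NumericVector bilinear_fwd(NumericVector x, int Ho, int Wo) {
  IntegerVector xd = tensor_dim(x);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  std::vector<int> y0, y1, x0, x1;
  std::vector<double> wy, wx;
  bilin_axis(H, Ho, y0, y1, wy);
  bilin_axis(W, Wo, x0, x1, wx);
  NumericVector y(no_init((size_t)Ho * Wo * C * N));
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (int q = 0; q < C * N; ++q) {
    const double *src = x.begin() + (size_t)H * W * q;
    double *dst = y.begin() + (size_t)Ho * Wo * q;
    for (int ox = 0; ox < Wo; ++ox) {
      const double *cl = src + (size_t)H * x0[ox];
      const double *cr = src + (size_t)H * x1[ox];
      double *out = dst + (size_t)Ho * ox;
      double a = wx[ox];
      for (int oy = 0; oy < Ho; ++oy) {
        double b = wy[oy];
        double top = cl[y0[oy]] * (1 - a) + cr[y0[oy]] * a;
        double bot = cl[y1[oy]] * (1 - a) + cr[y1[oy]] * a;
        out[oy] = top * (1 - b) + bot * b;
      }
    }
  }
  return y;
}

// [[Rcpp::export(name = ".bilinear_bwd")]]
NumericVector bilinear_bwd(NumericVector gy, int H, int W) {
  IntegerVector gd = tensor_dim(gy);
  int Ho = gd[0], Wo = gd[1], C = gd[2], N = gd[3];
  std::vector<int> y0, y1, x0, x1;
  std::vector<double> wy, wx;
  bilin_axis(H, Ho, y0, y1, wy);
  bilin_axis(W, Wo, x0, x1, wx);
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int q = 0; q < C * N; ++q) {
    const double *src = gy.begin() + (size_t)Ho * Wo * q;
    double *dst = gx.begin() + (size_t)H * W * q;
    for (int ox = 0; ox < Wo; ++ox) {
      double a = wx[ox];
      double *cl = dst + (size_t)H * x0[ox];
      double *cr = dst + (size_t)H * x1[ox];
      const double *g = src + (size_t)Ho * ox;
      for (int oy = 0; oy < Ho; ++oy) {
        double b = wy[oy];
        cl[y0[oy]] += g[oy] * (1 - a) * (1 - b);
        cr[y0[oy]] += g[oy] * a * (1 - b);
        cl[y1[oy]] += g[oy] * (1 - a) * b;
        cr[y1[oy]] += g[oy] * a * b;
      }
    }
  }
  return gx;
}

// Adaptive average pooling: output cell i covers rows floor(i*H/b) to
// ceil((i+1)*H/b) - 1, the PSPNet/torch convention.
// [[Rcpp::export(name = ".adapool_fwd")]]
NumericVector adapool_fwd(NumericVector x, int bh, int bw) {
  IntegerVector xd = tensor_dim(x);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  NumericVector y(no_init((size_t)bh * bw * C * N));
  y.attr("dim") = IntegerVector::create(bh, bw, C, N);
  for (int q = 0; q < C * N; ++q) {
    const double *src = x.begin() + (size_t)H * W * q;
    double *dst = y.begin() + (size_t)bh * bw * q;
    for (int ox = 0; ox < bw; ++ox) {
      int ws = (int)std::floor((double)ox * W / bw);
      int we = (int)std::ceil((double)(ox + 1) * W / bw);
      for (int oy = 0; oy < bh; ++oy) {
        int hs = (int)std::floor((double)oy * H / bh);
        int he = (int)std::ceil((double)(oy + 1) * H / bh);
        double s = 0;
        for (int w = ws; w < we; ++w)
          for (int h = hs; h < he; ++h) s += src[h + (size_t)H * w];
        dst[oy + (size_t)bh * ox] = s / ((he - hs) * (we - ws));
      }
    }
  }
  return y;
}

// [[Rcpp::export(name = ".adapool_bwd")]]
NumericVector adapool_bwd(NumericVector gy, int H, int W) {
  IntegerVector gd = tensor_dim(gy);
  int bh = gd[0], bw = gd[1], C = gd[2], N = gd[3];
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int q = 0; q < C * N; ++q) {
    const double *src = gy.begin() + (size_t)bh * bw * q;
    double *dst = gx.begin() + (size_t)H * W * q;
    for (int ox = 0; ox < bw; ++ox) {
      int ws = (int)std::floor((double)ox * W / bw);
      int we = (int)std::ceil((double)(ox + 1) * W / bw);
      for (int oy = 0; oy < bh; ++oy) {
        int hs = (int)std::floor((double)oy * H / bh);
        int he = (int)std::ceil((double)(oy + 1) * H / bh);
        double g = src[oy + (size_t)bh * ox] / ((he - hs) * (we - ws));
        for (int w = ws; w < we; ++w)
          for (int h = hs; h < he; ++h) dst[h + (size_t)H * w] += g;
      }
    }
  }
  return gx;
}

// Nearest-neighbour resampling of a 2-D matrix (used for label masks, where
// interpolation would create non-binary values).
// [[Rcpp::export(name = ".nearest_resize")]]
NumericMatrix nearest_resize(NumericMatrix x, int Ho, int Wo) {
  int H = x.nrow(), W = x.ncol();
  NumericMatrix y(Ho, Wo);
  for (int ox = 0; ox < Wo; ++ox) {
    int w = std::min((int)std::floor((ox + 0.5) * W / Wo), W - 1);
    for (int oy = 0; oy < Ho; ++oy) {
      int h = std::min((int)std::floor((oy + 0.5) * H / Ho), H - 1);
      y(oy, ox) = x(h, w);
    }
  }
  return y;
}
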