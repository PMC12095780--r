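// Low-level tensor kernels for the network core.
// Layout: feature maps are H x W x C x N arrays (column-major, R order);
// dense kernels are kh x kw x Cin x Cout; depthwise kernels kh x kw x C.
// "Same" zero padding: pad = (k - 1) * dilation / 2 per side (odd k only),
// so dilation never changes spatial size.
//
// Convolutions are computed tap by tap as shifted-rectangle accumulations:
// for each kernel tap the valid output window is a rectangle, so the inner
// loops are branch-free and run down contiguous columns.
#include <Rcpp.h>
using namespace Rcpp;

static inline R_xlen_t plane(int c, int n, int H, int W, int C) {
  return (R_xlen_t)H * W * (c + (R_xlen_t)C * n);
}

// valid output range [lo, hi) along one axis for tap offset `off` = k*d - p
static inline void axis_range(int off, int len, int &lo, int &hi) {
  lo = off < 0 ? -off : 0;
  hi = off > 0 ? len - off : len;
  if (hi < lo) hi = lo;
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fw(NumericVector x, IntegerVector xdim,
                            NumericVector w, IntegerVector wdim,
                            NumericVector b, int dh, int dw) {
  const int H = xdim[0], W = xdim[1], Cin = xdim[2], N = xdim[3];
  const int kh = wdim[0], kw = wdim[1], Cout = wdim[3];
  const int ph = (kh - 1) * dh / 2, pw = (kw - 1) * dw / 2;
  NumericVector y((R_xlen_t)H * W * Cout * N);
  const double *px = x.begin(), *pw_ = w.begin(), *pb = b.begin();
  double *py = y.begin();
  const bool has_b = b.size() > 0;
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      double *yp = py + plane(co, n, H, W, Cout);
      if (has_b) {
        const double bias = pb[co];
        for (R_xlen_t k = 0; k < (R_xlen_t)H * W; ++k) yp[k] = bias;
      }
      for (int ci = 0; ci < Cin; ++ci) {
        const double *xp = px + plane(ci, n, H, W, Cin);
        for (int b2 = 0; b2 < kw; ++b2) {
          const int offj = b2 * dw - pw;
          int jlo, jhi; axis_range(offj, W, jlo, jhi);
          for (int a = 0; a < kh; ++a) {
            const int offi = a * dh - ph;
            int ilo, ihi; axis_range(offi, H, ilo, ihi);
            const double wv = pw_[a + (R_xlen_t)kh * (b2 + (R_xlen_t)kw * (ci + (R_xlen_t)Cin * co))];
            if (wv == 0.0) continue;
            for (int j = jlo; j < jhi; ++j) {
              double *yc = yp + (R_xlen_t)H * j + ilo;
              const double *xc = xp + (R_xlen_t)H * (j + offj) + ilo + offi;
              const int len = ihi - ilo;
              for (int i = 0; i < len; ++i) yc[i] += wv * xc[i];
            }
          }
        }
      }
    }
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bw(NumericVector x, IntegerVector xdim,
                   NumericVector w, IntegerVector wdim,
                   NumericVector gy, int dh, int dw, bool has_bias) {
  const int H = xdim[0], W = xdim[1], Cin = xdim[2], N = xdim[3];
  const int kh = wdim[0], kw = wdim[1], Cout = wdim[3];
  const int ph = (kh - 1) * dh / 2, pw = (kw - 1) * dw / 2;
  NumericVector gx((R_xlen_t)H * W * Cin * N), gw(w.size()), gb(has_bias ? Cout : 0);
  const double *px = x.begin(), *pw_ = w.begin(), *pgy = gy.begin();
  double *pgx = gx.begin(), *pgw = gw.begin();
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      const double *gp = pgy + plane(co, n, H, W, Cout);
      if (has_bias) {
        double acc = 0.0;
        for (R_xlen_t k = 0; k < (R_xlen_t)H * W; ++k) acc += gp[k];
        gb[co] += acc;
      }
      for (int ci = 0; ci < Cin; ++ci) {
        const double *xp = px + plane(ci, n, H, W, Cin);
        double *gxp = pgx + plane(ci, n, H, W, Cin);
        for (int b2 = 0; b2 < kw; ++b2) {
          const int offj = b2 * dw - pw;
          int jlo, jhi; axis_range(offj, W, jlo, jhi);
          for (int a = 0; a < kh; ++a) {
            const int offi = a * dh - ph;
            int ilo, ihi; axis_range(offi, H, ilo, ihi);
            const R_xlen_t wi = a + (R_xlen_t)kh * (b2 + (R_xlen_t)kw * (ci + (R_xlen_t)Cin * co));
            const double wv = pw_[wi];
            double wacc = 0.0;
            const int len = ihi - ilo;
            for (int j = jlo; j < jhi; ++j) {
              const double *gc = gp + (R_xlen_t)H * j + ilo;
              const double *xc = xp + (R_xlen_t)H * (j + offj) + ilo + offi;
              double *gxc = gxp + (R_xlen_t)H * (j + offj) + ilo + offi;
              for (int i = 0; i < len; ++i) {
                gxc[i] += wv * gc[i];
                wacc += gc[i] * xc[i];
              }
            }
            pgw[wi] += wacc;
          }
        }
      }
    }
  gx.attr("dim") = xdim;
  gw.attr("dim") = wdim;
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export]]
NumericVector cpp_dwconv2d_fw(NumericVector x, IntegerVector xdim,
                              NumericVector w, IntegerVector wdim,
                              NumericVector b, int dh, int dw) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int kh = wdim[0], kw = wdim[1];
  const int ph = (kh - 1) * dh / 2, pw = (kw - 1) * dw / 2;
  NumericVector y((R_xlen_t)H * W * C * N);
  const double *px = x.begin(), *pw_ = w.begin(), *pb = b.begin();
  double *py = y.begin();
  const bool has_b = b.size() > 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double *yp = py + plane(c, n, H, W, C);
      const double *xp = px + plane(c, n, H, W, C);
      if (has_b) {
        const double bias = pb[c];
        for (R_xlen_t k = 0; k < (R_xlen_t)H * W; ++k) yp[k] = bias;
      }
      for (int b2 = 0; b2 < kw; ++b2) {
        const int offj = b2 * dw - pw;
        int jlo, jhi; axis_range(offj, W, jlo, jhi);
        for (int a = 0; a < kh; ++a) {
          const int offi = a * dh - ph;
          int ilo, ihi; axis_range(offi, H, ilo, ihi);
          const double wv = pw_[a + (R_xlen_t)kh * (b2 + (R_xlen_t)kw * c)];
          const int len = ihi - ilo;
          for (int j = jlo; j < jhi; ++j) {
            double *yc = yp + (R_xlen_t)H * j + ilo;
            const double *xc = xp + (R_xlen_t)H * (j + offj) + ilo + offi;
            for (int i = 0; i < len; ++i) yc[i] += wv * xc[i];
          }
        }
      }
    }
  y.attr("dim") = xdim;
  return y;
}

// [[Rcpp::export]]
List cpp_dwconv2d_bw(NumericVector x, IntegerVector xdim,
                     NumericVector w, IntegerVector wdim,
                     NumericVector gy, int dh, int dw, bool has_bias) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int kh = wdim[0], kw = wdim[1];
  const int ph = (kh - 1) * dh / 2, pw = (kw - 1) * dw / 2;
  NumericVector gx((R_xlen_t)H * W * C * N), gw(w.size()), gb(has_bias ? C : 0);
  const double *px = x.begin(), *pw_ = w.begin(), *pgy = gy.begin();
  double *pgx = gx.begin(), *pgw = gw.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double *gp = pgy + plane(c, n, H, W, C);
      const double *xp = px + plane(c, n, H, W, C);
      double *gxp = pgx + plane(c, n, H, W, C);
      if (has_bias) {
        double acc = 0.0;
        for (R_xlen_t k = 0; k < (R_xlen_t)H * W; ++k) acc += gp[k];
        gb[c] += acc;
      }
      for (int b2 = 0; b2 < kw; ++b2) {
        const int offj = b2 * dw - pw;
        int jlo, jhi; axis_range(offj, W, jlo, jhi);
        for (int a = 0; a < kh; ++a) {
          const int offi = a * dh - ph;
          int ilo, ihi; axis_range(offi, H, ilo, ihi);
          const R_xlen_t wi = a + (R_xlen_t)kh * (b2 + (R_xlen_t)kw * c);
          const double wv = pw_[wi];
          double wacc = 0.0;
          const int len = ihi - ilo;
          for (int j = jlo; j < jhi; ++j) {
            const double *gc = gp + (R_xlen_t)H * j + ilo;
            const double *xc = xp + (R_xlen_t)H * (j + offj) + ilo + offi;
            double *gxc = gxp + (R_xlen_t)H * (j + offj) + ilo + offi;
            for (int i = 0; i < len; ++i) {
              gxc[i] += wv * gc[i];
              wacc += gc[i] * xc[i];
            }
          }
          pgw[wi] += wacc;
        }
      }
    }
  gx.attr("dim") = xdim;
  gw.attr("dim") = wdim;
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export]]
List cpp_maxpool2_fw(NumericVector x, IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  IntegerVector idx(y.size());  // 0-based linear index into x of the argmax
  const double *px = x.begin();
  double *py = y.begin();
  int *pidx = idx.begin();
  R_xlen_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const R_xlen_t base = plane(c, n, H, W, C);
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i, ++o) {
          R_xlen_t k00 = base + (R_xlen_t)H * (2 * j) + 2 * i;
          R_xlen_t best = k00;
          if (px[k00 + 1] > px[best]) best = k00 + 1;
          if (px[k00 + H] > px[best]) best = k00 + H;
          if (px[k00 + H + 1] > px[best]) best = k00 + H + 1;
          py[o] = px[best];
          pidx[o] = (int)best;
        }
    }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bw(NumericVector gy, IntegerVector idx, IntegerVector xdim) {
  NumericVector gx((R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  const double *pgy = gy.begin();
  const int *pidx = idx.begin();
  double *pgx = gx.begin();
  for (R_xlen_t k = 0; k < gy.size(); ++k) pgx[pidx[k]] += pgy[k];
  gx.attr("dim") = xdim;
  return gx;
}

// Transpose convolution, kernel 2x2, stride 2: exact x2 upsampling.
// [[Rcpp::export]]
NumericVector cpp_convtr2_fw(NumericVector x, IntegerVector xdim,
                             NumericVector w, IntegerVector wdim, NumericVector b) {
  const int H = xdim[0], W = xdim[1], Cin = xdim[2], N = xdim[3];
  const int Cout = wdim[3];
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector y((R_xlen_t)Ho * Wo * Cout * N);
  const double *px = x.begin(), *pw_ = w.begin(), *pb = b.begin();
  double *py = y.begin();
  const bool has_b = b.size() > 0;
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      double *yp = py + plane(co, n, Ho, Wo, Cout);
      if (has_b) {
        const double bias = pb[co];
        for (R_xlen_t k = 0; k < (R_xlen_t)Ho * Wo; ++k) yp[k] = bias;
      }
      for (int ci = 0; ci < Cin; ++ci) {
        const double *xp = px + plane(ci, n, H, W, Cin);
        for (int kj = 0; kj < 2; ++kj)
          for (int ki = 0; ki < 2; ++ki) {
            const double wv = pw_[ki + 2 * (kj + 2 * (ci + (R_xlen_t)Cin * co))];
            if (wv == 0.0) continue;
            for (int j = 0; j < W; ++j) {
              const double *xc = xp + (R_xlen_t)H * j;
              double *yc = yp + (R_xlen_t)Ho * (2 * j + kj) + ki;
              for (int i = 0; i < H; ++i) yc[2 * i] += wv * xc[i];
            }
          }
      }
    }
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  return y;
}

// [[Rcpp::export]]
List cpp_convtr2_bw(NumericVector x, IntegerVector xdim,
                    NumericVector w, IntegerVector wdim,
                    NumericVector gy, bool has_bias) {
  const int H = xdim[0], W = xdim[1], Cin = xdim[2], N = xdim[3];
  const int Cout = wdim[3];
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector gx((R_xlen_t)H * W * Cin * N), gw(w.size()), gb(has_bias ? Cout : 0);
  const double *px = x.begin(), *pw_ = w.begin(), *pgy = gy.begin();
  double *pgx = gx.begin(), *pgw = gw.begin();
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      const double *gp = pgy + plane(co, n, Ho, Wo, Cout);
      if (has_bias) {
        double acc = 0.0;
        for (R_xlen_t k = 0; k < (R_xlen_t)Ho * Wo; ++k) acc += gp[k];
        gb[co] += acc;
      }
      for (int ci = 0; ci < Cin; ++ci) {
        const double *xp = px + plane(ci, n, H, W, Cin);
        double *gxp = pgx + plane(ci, n, H, W, Cin);
        for (int kj = 0; kj < 2; ++kj)
          for (int ki = 0; ki < 2; ++ki) {
            const R_xlen_t wi = ki + 2 * (kj + 2 * (ci + (R_xlen_t)Cin * co));
            const double wv = pw_[wi];
            double wacc = 0.0;
            for (int j = 0; j < W; ++j) {
              const double *gc = gp + (R_xlen_t)Ho * (2 * j + kj) + ki;
              const double *xc = xp + (R_xlen_t)H * j;
              double *gxc = gxp + (R_xlen_t)H * j;
              for (int i = 0; i < H; ++i) {
                gxc[i] += wv * gc[2 * i];
                wacc += gc[2 * i] * xc[i];
              }
            }
            pgw[wi] += wacc;
          }
      }
    }
  gx.attr("dim") = xdim;
  gw.attr("dim") = wdim;
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// ---- batch-normalization helpers -------------------------------------------

// per-channel sum and sum of squares over (H, W, N)
// [[Rcpp::export]]
List cpp_chan_stats(NumericVector x, IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  NumericVector s(C), ss(C);
  const double *px = x.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double *xp = px + plane(c, n, H, W, C);
      double a = 0.0, a2 = 0.0;
      for (R_xlen_t k = 0; k < (R_xlen_t)H * W; ++k) { a += xp[k]; a2 += xp[k] * xp[k]; }
      s[c] += a; ss[c] += a2;
    }
  return List::create(_["sum"] = s, _["sumsq"] = ss);
}

// y = x * a[c] + b[c], broadcast per channel
// [[Rcpp::export]]
NumericVector cpp_chan_affine(NumericVector x, IntegerVector xdim,
                              NumericVector a, NumericVector b) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  NumericVector y(x.size());
  const double *px = x.begin(), *pa = a.begin(), *pb = b.begin();
  double *py = y.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double ac = pa[c], bc = pb[c];
      const double *xp = px + plane(c, n, H, W, C);
      double *yp = py + plane(c, n, H, W, C);
      for (R_xlen_t k = 0; k < (R_xlen_t)H * W; ++k) yp[k] = xp[k] * ac + bc;
    }
  y.attr("dim") = xdim;
  return y;
}

// full training-mode batch-norm input gradient:
// gx = (g*gamma[c] - mean_c(g*gamma) - xhat * mean_c(g*gamma*xhat)) * istd[c]
// also returns dgamma = sum_c(g * xhat) and dbeta = sum_c(g)
// [[Rcpp::export]]
List cpp_bn_bw(NumericVector g, NumericVector xhat, IntegerVector xdim,
               NumericVector gamma, NumericVector istd, bool training) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const double m = (double)H * W * N;
  NumericVector gx(g.size()), dgamma(C), dbeta(C);
  const double *pg = g.begin(), *ph_ = xhat.begin();
  double *pgx = gx.begin();
  // first pass: per-channel sums of g and g*xhat
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double *gp = pg + plane(c, n, H, W, C);
      const double *hp = ph_ + plane(c, n, H, W, C);
      double sg = 0.0, sgh = 0.0;
      for (R_xlen_t k = 0; k < (R_xlen_t)H * W; ++k) { sg += gp[k]; sgh += gp[k] * hp[k]; }
      dbeta[c] += sg; dgamma[c] += sgh;
    }
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double *gp = pg + plane(c, n, H, W, C);
      const double *hp = ph_ + plane(c, n, H, W, C);
      double *gxp = pgx + plane(c, n, H, W, C);
      const double gam = gamma[c], is = istd[c];
      if (training) {
        const double mg = dbeta[c] / m, mgh = dgamma[c] / m;
        for (R_xlen_t k = 0; k < (R_xlen_t)H * W; ++k)
          gxp[k] = (gp[k] - mg - hp[k] * mgh) * gam * is;
      } else {
        for (R_xlen_t k = 0; k < (R_xlen_t)H * W; ++k)
          gxp[k] = gp[k] * gam * is;
      }
    }
  gx.attr("dim") = xdim;
  return List::create(_["gx"] = gx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}
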