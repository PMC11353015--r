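// Dense-linear-algebra kernels for the CNN layers: grouped 2-D convolution
// (im2col + GEMM), max pooling, and their gradients. Tensors are passed as
// flat numeric vectors in (H, W, C, N) column-major layout. Hot loops use
// raw pointers; the h-axis is contiguous, so patch rows are copied as runs.
#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

typedef arma::uword uw;

static inline uw idx4(uw h, uw w, uw c, uw n, uw H, uw W, uw C) {
  return h + H * (w + W * (c + C * n));
}

// Gather input patches for one channel-group into a (kh*kw*Cg) x (Ho*Wo*N)
// matrix. Zero padding of width `pad` on every side.
static arma::mat im2col_group(const double *x, uw H, uw W, uw C, uw N, uw c0,
                              uw Cg, uw kh, uw kw, uw stride, uw pad, uw Ho,
                              uw Wo) {
  arma::mat col(kh * kw * Cg, Ho * Wo * N, arma::fill::zeros);
  double *cp = col.memptr();
  const uw rows = kh * kw * Cg;
  for (uw n = 0; n < N; ++n) {
    for (uw wo = 0; wo < Wo; ++wo) {
      for (uw ho = 0; ho < Ho; ++ho) {
        double *dst0 = cp + rows * (ho + Ho * (wo + Wo * n));
        const long h0 = (long)(ho * stride) - (long)pad;
        const long w0 = (long)(wo * stride) - (long)pad;
        const uw klo = (uw)std::max(0L, -h0);
        const uw khi_end = (uw)std::min((long)kh, (long)H - h0); // exclusive
        if (khi_end <= klo) continue;
        for (uw c = 0; c < Cg; ++c) {
          const double *xc = x + H * W * (c0 + c + C * n);
          for (uw kj = 0; kj < kw; ++kj) {
            const long wi = w0 + (long)kj;
            if (wi < 0 || wi >= (long)W) continue;
            std::memcpy(dst0 + klo + kh * (kj + kw * c),
                        xc + (uw)(h0 + (long)klo) + H * (uw)wi,
                        (khi_end - klo) * sizeof(double));
          }
        }
      }
    }
  }
  return col;
}

// Scatter-add a patch matrix back into image space (adjoint of im2col_group).
static void col2im_group(const arma::mat &col, double *dx, uw H, uw W, uw C,
                         uw N, uw c0, uw Cg, uw kh, uw kw, uw stride, uw pad,
                         uw Ho, uw Wo) {
  const double *cp = col.memptr();
  const uw rows = kh * kw * Cg;
  for (uw n = 0; n < N; ++n) {
    for (uw wo = 0; wo < Wo; ++wo) {
      for (uw ho = 0; ho < Ho; ++ho) {
        const double *src0 = cp + rows * (ho + Ho * (wo + Wo * n));
        const long h0 = (long)(ho * stride) - (long)pad;
        const long w0 = (long)(wo * stride) - (long)pad;
        const uw klo = (uw)std::max(0L, -h0);
        const uw khi_end = (uw)std::min((long)kh, (long)H - h0);
        if (khi_end <= klo) continue;
        for (uw c = 0; c < Cg; ++c) {
          double *xc = dx + H * W * (c0 + c + C * n);
          for (uw kj = 0; kj < kw; ++kj) {
            const long wi = w0 + (long)kj;
            if (wi < 0 || wi >= (long)W) continue;
            double *d = xc + (uw)(h0 + (long)klo) + H * (uw)wi;
            const double *s = src0 + klo + kh * (kj + kw * c);
            for (uw k = 0; k < khi_end - klo; ++k) d[k] += s[k];
          }
        }
      }
    }
  }
}

// x: (H,W,C,N); w: (kh,kw,Cin/groups,Cout); bias: length Cout or empty.
// [[Rcpp::export(name = ".conv2d_fw")]]
NumericVector conv2d_fw(NumericVector x, IntegerVector xdim, NumericVector w,
                        IntegerVector wdim, NumericVector bias, int stride,
                        int pad, int groups) {
  uw H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  uw kh = wdim[0], kw = wdim[1], Cg = wdim[2], Cout = wdim[3];
  if (Cg * (uw)groups != C) stop("channel/group mismatch");
  if (Cout % groups != 0) stop("out-channel/group mismatch");
  uw Ho = (H + 2 * pad - kh) / stride + 1;
  uw Wo = (W + 2 * pad - kw) / stride + 1;
  uw Coutg = Cout / groups;
  arma::mat wm(w.begin(), kh * kw * Cg, Cout, false);
  NumericVector y((R_xlen_t)(Ho * Wo * Cout * N));
  double *yp = y.begin();
  const bool has_bias = bias.size() > 0;
  for (int g = 0; g < groups; ++g) {
    arma::mat col = im2col_group(x.begin(), H, W, C, N, g * Cg, Cg, kh, kw,
                                 (uw)stride, (uw)pad, Ho, Wo);
    arma::mat out = wm.cols(g * Coutg, (g + 1) * Coutg - 1).t() * col;
    const double *op = out.memptr(); // (Coutg, Ho*Wo*N) column-major
    const uw HoWo = Ho * Wo;
    for (uw n = 0; n < N; ++n) {
      for (uw co = 0; co < Coutg; ++co) {
        const uw cglob = g * Coutg + co;
        const double b = has_bias ? bias[cglob] : 0.0;
        double *yd = yp + HoWo * (cglob + Cout * n);
        const double *os = op + co + Coutg * HoWo * n;
        for (uw q = 0; q < HoWo; ++q) yd[q] = os[Coutg * q] + b;
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  return y;
}

// [[Rcpp::export(name = ".conv2d_bw")]]
List conv2d_bw(NumericVector x, IntegerVector xdim, NumericVector w,
               IntegerVector wdim, NumericVector dy, int stride, int pad,
               int groups, bool need_dx) {
  uw H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  uw kh = wdim[0], kw = wdim[1], Cg = wdim[2], Cout = wdim[3];
  uw Ho = (H + 2 * pad - kh) / stride + 1;
  uw Wo = (W + 2 * pad - kw) / stride + 1;
  uw Coutg = Cout / groups;
  arma::mat wm(w.begin(), kh * kw * Cg, Cout, false);

  NumericVector dw(w.size()), db(Cout);
  arma::mat dwm(dw.begin(), kh * kw * Cg, Cout, false, true);
  NumericVector dx(need_dx ? x.size() : 0);
  const uw HoWo = Ho * Wo;
  const double *dyp = dy.begin();

  for (int g = 0; g < groups; ++g) {
    arma::mat col = im2col_group(x.begin(), H, W, C, N, g * Cg, Cg, kh, kw,
                                 (uw)stride, (uw)pad, Ho, Wo);
    arma::mat dyg(Coutg, HoWo * N);
    double *dgp = dyg.memptr();
    for (uw n = 0; n < N; ++n) {
      for (uw co = 0; co < Coutg; ++co) {
        const uw cglob = g * Coutg + co;
        const double *ds = dyp + HoWo * (cglob + Cout * n);
        double *dd = dgp + co + Coutg * HoWo * n;
        double acc = 0.0;
        for (uw q = 0; q < HoWo; ++q) {
          dd[Coutg * q] = ds[q];
          acc += ds[q];
        }
        db[cglob] += acc;
      }
    }
    dwm.cols(g * Coutg, (g + 1) * Coutg - 1) = col * dyg.t();
    if (need_dx) {
      arma::mat dcol = wm.cols(g * Coutg, (g + 1) * Coutg - 1) * dyg;
      col2im_group(dcol, dx.begin(), H, W, C, N, g * Cg, Cg, kh, kw,
                   (uw)stride, (uw)pad, Ho, Wo);
    }
  }
  dw.attr("dim") = wdim;
  if (need_dx) dx.attr("dim") = xdim;
  return List::create(Named("dx") = dx, Named("dw") = dw, Named("db") = db);
}

// [[Rcpp::export(name = ".maxpool_fw")]]
List maxpool_fw(NumericVector x, IntegerVector xdim, int size, int stride) {
  uw H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  uw Ho = (H - size) / stride + 1, Wo = (W - size) / stride + 1;
  NumericVector y((R_xlen_t)(Ho * Wo * C * N));
  IntegerVector amax(y.size());
  const double *xp = x.begin();
  double *yp = y.begin();
  int *ap = amax.begin();
  for (uw n = 0; n < N; ++n)
    for (uw c = 0; c < C; ++c) {
      const double *xc = xp + H * W * (c + C * n);
      const uw base = H * W * (c + C * n);
      for (uw wo = 0; wo < Wo; ++wo)
        for (uw ho = 0; ho < Ho; ++ho) {
          double best = -std::numeric_limits<double>::infinity();
          uw besti = 0;
          for (uw kj = 0; kj < (uw)size; ++kj) {
            const double *xw = xc + ho * stride + H * (wo * stride + kj);
            for (uw ki = 0; ki < (uw)size; ++ki)
              if (xw[ki] > best) {
                best = xw[ki];
                besti = base + ho * stride + ki + H * (wo * stride + kj);
              }
          }
          const uw o = ho + Ho * (wo + Wo * (c + C * n));
          yp[o] = best;
          ap[o] = (int)besti;
        }
    }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return List::create(Named("y") = y, Named("argmax") = amax);
}

// [[Rcpp::export(name = ".maxpool_bw")]]
NumericVector maxpool_bw(NumericVector dy, IntegerVector argmax,
                         IntegerVector xdim) {
  NumericVector dx((R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  double *dxp = dx.begin();
  const double *dyp = dy.begin();
  const int *ap = argmax.begin();
  for (R_xlen_t i = 0; i < dy.size(); ++i) dxp[ap[i]] += dyp[i];
  dx.attr("dim") = xdim;
  return dx;
}
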