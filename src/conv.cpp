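// Grouped 2D convolution (forward / backward) on (H, W, C, B) column-major
// arrays, via per-group im2col + BLAS gemm. Used by the autodiff tape; the
// same routine serves dense, depthwise and strip (1 x k / k x 1) convolutions.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static void im2col(const double* x, int H, int W, int C, int b,
                   int c0, int Cg, int kh, int kw, int sh, int sw,
                   int ph, int pw, int Ho, int Wo, arma::mat& col) {
  const double* xb = x + (size_t)H * W * C * b;
  for (int ci = 0; ci < Cg; ++ci) {
    const double* xc = xb + (size_t)H * W * (c0 + ci);
    for (int dw = 0; dw < kw; ++dw) {
      for (int dh = 0; dh < kh; ++dh) {
        const int r = dh + kh * (dw + kw * ci);
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * sw - pw + dw;
          double* cr = col.colptr(0) + r; // col is (R x HoWo), advance by R
          if (wi < 0 || wi >= W) {
            for (int ho = 0; ho < Ho; ++ho)
              col(r, ho + (size_t)Ho * wo) = 0.0;
            continue;
          }
          const double* xcw = xc + (size_t)H * wi;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hi = ho * sh - ph + dh;
            col(r, ho + (size_t)Ho * wo) =
                (hi >= 0 && hi < H) ? xcw[hi] : 0.0;
          }
          (void)cr;
        }
      }
    }
  }
}

static void col2im_add(double* dx, int H, int W, int C, int b,
                       int c0, int Cg, int kh, int kw, int sh, int sw,
                       int ph, int pw, int Ho, int Wo, const arma::mat& dcol) {
  double* xb = dx + (size_t)H * W * C * b;
  for (int ci = 0; ci < Cg; ++ci) {
    double* xc = xb + (size_t)H * W * (c0 + ci);
    for (int dw = 0; dw < kw; ++dw) {
      for (int dh = 0; dh < kh; ++dh) {
        const int r = dh + kh * (dw + kw * ci);
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * sw - pw + dw;
          if (wi < 0 || wi >= W) continue;
          double* xcw = xc + (size_t)H * wi;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hi = ho * sh - ph + dh;
            if (hi >= 0 && hi < H)
              xcw[hi] += dcol(r, ho + (size_t)Ho * wo);
          }
        }
      }
    }
  }
}

// direct depthwise convolution (groups == C_in == C_out), no im2col
static void dw_fwd(const double* x, int H, int W, int C, int B,
                   const double* w, int kh, int kw, int sh, int sw,
                   int ph, int pw, int Ho, int Wo, const double* bias,
                   bool has_bias, double* y) {
  for (int b = 0; b < B; ++b) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x + (size_t)H * W * (c + (size_t)C * b);
      const double* wc = w + (size_t)kh * kw * c;
      double* yc = y + (size_t)Ho * Wo * (c + (size_t)C * b);
      const double bv = has_bias ? bias[c] : 0.0;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double s = bv;
          const int h0 = ho * sh - ph, w0 = wo * sw - pw;
          for (int dw_ = 0; dw_ < kw; ++dw_) {
            const int wi = w0 + dw_;
            if (wi < 0 || wi >= W) continue;
            const double* xw = xc + (size_t)H * wi;
            const double* ww = wc + (size_t)kh * dw_;
            for (int dh = 0; dh < kh; ++dh) {
              const int hi = h0 + dh;
              if (hi >= 0 && hi < H) s += xw[hi] * ww[dh];
            }
          }
          yc[ho + (size_t)Ho * wo] = s;
        }
      }
    }
  }
}

static void dw_bwd(const double* x, int H, int W, int C, int B,
                   const double* w, int kh, int kw, int sh, int sw,
                   int ph, int pw, int Ho, int Wo, const double* gy,
                   double* dx, double* dwt, double* db, bool has_bias) {
  for (int b = 0; b < B; ++b) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x + (size_t)H * W * (c + (size_t)C * b);
      const double* wc = w + (size_t)kh * kw * c;
      const double* gc = gy + (size_t)Ho * Wo * (c + (size_t)C * b);
      double* dxc = dx + (size_t)H * W * (c + (size_t)C * b);
      double* dwc = dwt + (size_t)kh * kw * c;
      double dbs = 0.0;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          const double g = gc[ho + (size_t)Ho * wo];
          dbs += g;
          const int h0 = ho * sh - ph, w0 = wo * sw - pw;
          for (int dw_ = 0; dw_ < kw; ++dw_) {
            const int wi = w0 + dw_;
            if (wi < 0 || wi >= W) continue;
            for (int dh = 0; dh < kh; ++dh) {
              const int hi = h0 + dh;
              if (hi < 0 || hi >= H) continue;
              dxc[hi + (size_t)H * wi] += g * wc[dh + (size_t)kh * dw_];
              dwc[dh + (size_t)kh * dw_] += g * xc[hi + (size_t)H * wi];
            }
          }
        }
      }
      if (has_bias) db[c] += dbs;
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, IntegerVector xd,
                             NumericVector w, IntegerVector wd,
                             NumericVector bias, IntegerVector stride,
                             IntegerVector pad, int groups) {
  const int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  const int kh = wd[0], kw = wd[1], Cg = wd[2], Cout = wd[3];
  const int sh = stride[0], sw = stride[1], ph = pad[0], pw = pad[1];
  const int Ho = (H + 2 * ph - kh) / sh + 1;
  const int Wo = (W + 2 * pw - kw) / sw + 1;
  const int cog = Cout / groups;
  const int R = kh * kw * Cg;
  const size_t HoWo = (size_t)Ho * Wo;

  NumericVector y(HoWo * Cout * B);
  if (kh == 1 && kw == 1 && sh == 1 && sw == 1 && groups == 1) {
    // pointwise convolution == per-batch gemm on the (HW x C) slice
    arma::mat Wm1(w.begin(), C, Cout, false, true);
    for (int b = 0; b < B; ++b) {
      arma::mat Xb(x.begin() + (size_t)H * W * C * b, (size_t)H * W, C,
                   false, true);
      arma::mat Yb(y.begin() + HoWo * (size_t)Cout * b, HoWo, Cout,
                   false, true);
      Yb = Xb * Wm1;
    }
    if (bias.size() == Cout) {
      for (int b = 0; b < B; ++b)
        for (int co = 0; co < Cout; ++co) {
          double* yp = y.begin() + HoWo * ((size_t)Cout * b + co);
          const double bv = bias[co];
          for (size_t i = 0; i < HoWo; ++i) yp[i] += bv;
        }
    }
    y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, B);
    return y;
  }
  if (groups == C && Cg == 1 && Cout == C) {
    dw_fwd(x.begin(), H, W, C, B, w.begin(), kh, kw, sh, sw, ph, pw,
           Ho, Wo, bias.begin(), bias.size() == Cout, y.begin());
    y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, B);
    return y;
  }
  arma::mat col(R, HoWo);
  arma::mat Wm(w.begin(), R, Cout, false, true);

  for (int b = 0; b < B; ++b) {
    for (int g = 0; g < groups; ++g) {
      im2col(x.begin(), H, W, C, b, g * Cg, Cg, kh, kw, sh, sw, ph, pw,
             Ho, Wo, col);
      arma::mat Yg(y.begin() + HoWo * ((size_t)Cout * b + (size_t)g * cog),
                   HoWo, cog, false, true);
      Yg = col.t() * Wm.cols(g * cog, (g + 1) * cog - 1);
    }
  }
  if (bias.size() == Cout) {
    for (int b = 0; b < B; ++b)
      for (int co = 0; co < Cout; ++co) {
        double* yp = y.begin() + HoWo * ((size_t)Cout * b + co);
        const double bv = bias[co];
        for (size_t i = 0; i < HoWo; ++i) yp[i] += bv;
      }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, B);
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, IntegerVector xd,
                    NumericVector w, IntegerVector wd,
                    NumericVector gy, IntegerVector stride,
                    IntegerVector pad, int groups, bool has_bias) {
  const int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  const int kh = wd[0], kw = wd[1], Cg = wd[2], Cout = wd[3];
  const int sh = stride[0], sw = stride[1], ph = pad[0], pw = pad[1];
  const int Ho = (H + 2 * ph - kh) / sh + 1;
  const int Wo = (W + 2 * pw - kw) / sw + 1;
  const int cog = Cout / groups;
  const int R = kh * kw * Cg;
  const size_t HoWo = (size_t)Ho * Wo;

  NumericVector dx(x.size());
  NumericVector dw(w.size());
  NumericVector db(has_bias ? Cout : 0);
  if (kh == 1 && kw == 1 && sh == 1 && sw == 1 && groups == 1) {
    arma::mat Wm1(w.begin(), C, Cout, false, true);
    arma::mat dW1(dw.begin(), C, Cout, false, true);
    for (int b = 0; b < B; ++b) {
      arma::mat Xb(x.begin() + (size_t)H * W * C * b, (size_t)H * W, C,
                   false, true);
      arma::mat Gb(gy.begin() + HoWo * (size_t)Cout * b, HoWo, Cout,
                   false, true);
      arma::mat dXb(dx.begin() + (size_t)H * W * C * b, (size_t)H * W, C,
                    false, true);
      dXb = Gb * Wm1.t();
      dW1 += Xb.t() * Gb;
    }
    if (has_bias) {
      for (int b = 0; b < B; ++b)
        for (int co = 0; co < Cout; ++co) {
          const double* gp = gy.begin() + HoWo * ((size_t)Cout * b + co);
          double s = 0.0;
          for (size_t i = 0; i < HoWo; ++i) s += gp[i];
          db[co] += s;
        }
    }
    dx.attr("dim") = xd;
    dw.attr("dim") = wd;
    return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
  }
  if (groups == C && Cg == 1 && Cout == C) {
    dw_bwd(x.begin(), H, W, C, B, w.begin(), kh, kw, sh, sw, ph, pw,
           Ho, Wo, gy.begin(), dx.begin(), dw.begin(), db.begin(), has_bias);
    dx.attr("dim") = xd;
    dw.attr("dim") = wd;
    return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
  }
  arma::mat col(R, HoWo);
  arma::mat Wm(w.begin(), R, Cout, false, true);

  for (int b = 0; b < B; ++b) {
    for (int g = 0; g < groups; ++g) {
      im2col(x.begin(), H, W, C, b, g * Cg, Cg, kh, kw, sh, sw, ph, pw,
             Ho, Wo, col);
      arma::mat gY(gy.begin() + HoWo * ((size_t)Cout * b + (size_t)g * cog),
                   HoWo, cog, false, true);
      arma::mat dWg(dw.begin() + (size_t)R * g * cog, R, cog, false, true);
      dWg += col * gY;
      arma::mat dcol = Wm.cols(g * cog, (g + 1) * cog - 1) * gY.t();
      col2im_add(dx.begin(), H, W, C, b, g * Cg, Cg, kh, kw, sh, sw, ph, pw,
                 Ho, Wo, dcol);
    }
  }
  if (has_bias) {
    for (int b = 0; b < B; ++b)
      for (int co = 0; co < Cout; ++co) {
        const double* gp = gy.begin() + HoWo * ((size_t)Cout * b + co);
        double s = 0.0;
        for (size_t i = 0; i < HoWo; ++i) s += gp[i];
        db[co] += s;
      }
  }
  dx.attr("dim") = xd;
  dw.attr("dim") = wd;
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}
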