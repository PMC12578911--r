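// Low-level tensor kernels for the CPU layer backend.
//
// All feature maps are R arrays with dim (H, W, C, N), column-major.
// Sampling indices are 0-based row-major positions within one (C, N)
// plane of the full-resolution map, i.e. pos = row * W + col, so scatter
// operations are independent of any window bookkeeping.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline R_xlen_t off4(int h, int w, int c, int n, int H, int W, int C) {
  return (R_xlen_t)h + (R_xlen_t)H * (w + (R_xlen_t)W * (c + (R_xlen_t)C * n));
}

static void get_dim4(const NumericVector& x, int& H, int& W, int& C, int& N) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d array (H, W, C, N)");
  H = d[0]; W = d[1]; C = d[2]; N = d[3];
}

// ---------------------------------------------------------------------------
// Convolution (im2col + GEMM), with stride / padding / dilation / groups
// ---------------------------------------------------------------------------

static void im2col(const double* x, int H, int W, int C, int n,
                   int c0, int cg, int kh, int kw, int sh, int sw,
                   int ph, int pw, int dh, int dw, int oh, int ow,
                   arma::mat& col) {
  // col is (kh*kw*cg) x (oh*ow); row k = ci*kh*kw + kr*kw + kc,
  // column p = orow*ow + ocol (row-major over output cells)
  for (int ci = 0; ci < cg; ++ci) {
    const double* xc = x + off4(0, 0, c0 + ci, n, H, W, C);
    for (int kr = 0; kr < kh; ++kr) {
      for (int kc = 0; kc < kw; ++kc) {
        int k = ci * kh * kw + kr * kw + kc;
        for (int orow = 0; orow < oh; ++orow) {
          int ir = orow * sh - ph + kr * dh;
          for (int ocol = 0; ocol < ow; ++ocol) {
            int ic = ocol * sw - pw + kc * dw;
            double v = 0.0;
            if (ir >= 0 && ir < H && ic >= 0 && ic < W)
              v = xc[(R_xlen_t)ir + (R_xlen_t)H * ic];
            col(k, orow * ow + ocol) = v;
          }
        }
      }
    }
  }
}

static void col2im_add(double* gx, int H, int W, int C, int n,
                       int c0, int cg, int kh, int kw, int sh, int sw,
                       int ph, int pw, int dh, int dw, int oh, int ow,
                       const arma::mat& colg) {
  for (int ci = 0; ci < cg; ++ci) {
    double* xc = gx + off4(0, 0, c0 + ci, n, H, W, C);
    for (int kr = 0; kr < kh; ++kr) {
      for (int kc = 0; kc < kw; ++kc) {
        int k = ci * kh * kw + kr * kw + kc;
        for (int orow = 0; orow < oh; ++orow) {
          int ir = orow * sh - ph + kr * dh;
          if (ir < 0 || ir >= H) continue;
          for (int ocol = 0; ocol < ow; ++ocol) {
            int ic = ocol * sw - pw + kc * dw;
            if (ic < 0 || ic >= W) continue;
            xc[(R_xlen_t)ir + (R_xlen_t)H * ic] += colg(k, orow * ow + ocol);
          }
        }
      }
    }
  }
}

static arma::mat weight_mat(const NumericVector& w, int kh, int kw, int cg,
                            int coutg, int g) {
  // w has dim (kh, kw, cg, cout_total); slice the g-th block of coutg filters
  arma::mat Wm(coutg, kh * kw * cg);
  const double* wp = REAL(w);
  for (int col = 0; col < coutg; ++col) {
    int co = g * coutg + col;
    for (int ci = 0; ci < cg; ++ci)
      for (int kr = 0; kr < kh; ++kr)
        for (int kc = 0; kc < kw; ++kc) {
          R_xlen_t woff = (R_xlen_t)kr + (R_xlen_t)kh *
            (kc + (R_xlen_t)kw * (ci + (R_xlen_t)cg * co));
          Wm(col, ci * kh * kw + kr * kw + kc) = wp[woff];
        }
  }
  return Wm;
}

// [[Rcpp::export]]
NumericVector cpp_conv2d(NumericVector x, NumericVector w, NumericVector b,
                         int sh, int sw, int ph, int pw, int dh, int dw,
                         int groups) {
  int H, W, C, N; get_dim4(x, H, W, C, N);
  IntegerVector wd = w.attr("dim");
  int kh = wd[0], kw = wd[1], cg = wd[2], cout = wd[3];
  if (C != cg * groups) stop("input channels do not match weight shape/groups");
  if (kh == 1 && kw == 1 && sh == 1 && sw == 1 && ph == 0 && pw == 0 &&
      groups == 1) {
    // 1x1 convolution: plain per-sample GEMM on (H*W, C) views, no im2col
    NumericVector out((R_xlen_t)H * W * cout * N);
    out.attr("dim") = IntegerVector::create(H, W, cout, N);
    arma::mat Wm(REAL(w), C, cout, false, true);
    R_xlen_t plane = (R_xlen_t)H * W;
    for (int n = 0; n < N; ++n) {
      arma::mat X(REAL(x) + plane * C * n, plane, C, false, true);
      arma::mat O(REAL(out) + plane * cout * n, plane, cout, false, true);
      O = X * Wm;
      for (int co = 0; co < cout; ++co) O.col(co) += b[co];
    }
    return out;
  }
  int coutg = cout / groups;
  int oh = (H + 2 * ph - dh * (kh - 1) - 1) / sh + 1;
  int ow = (W + 2 * pw - dw * (kw - 1) - 1) / sw + 1;
  if (oh < 1 || ow < 1) stop("convolution output would be empty");
  NumericVector out((R_xlen_t)oh * ow * cout * N);
  out.attr("dim") = IntegerVector::create(oh, ow, cout, N);
  const double* xp = REAL(x);
  double* op = REAL(out);
  arma::mat col(kh * kw * cg, oh * ow);
  for (int g = 0; g < groups; ++g) {
    arma::mat Wm = weight_mat(w, kh, kw, cg, coutg, g);
    for (int n = 0; n < N; ++n) {
      im2col(xp, H, W, C, n, g * cg, cg, kh, kw, sh, sw, ph, pw, dh, dw, oh, ow, col);
      arma::mat O = Wm * col; // coutg x (oh*ow)
      for (int cl = 0; cl < coutg; ++cl) {
        int co = g * coutg + cl;
        double bb = b[co];
        double* oc = op + off4(0, 0, co, n, oh, ow, cout);
        for (int orow = 0; orow < oh; ++orow)
          for (int ocol = 0; ocol < ow; ++ocol)
            oc[(R_xlen_t)orow + (R_xlen_t)oh * ocol] = O(cl, orow * ow + ocol) + bb;
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_conv2d_backward(NumericVector x, NumericVector w, NumericVector gout,
                         int sh, int sw, int ph, int pw, int dh, int dw,
                         int groups) {
  int H, W, C, N; get_dim4(x, H, W, C, N);
  IntegerVector wd = w.attr("dim");
  int kh = wd[0], kw = wd[1], cg = wd[2], cout = wd[3];
  int coutg = cout / groups;
  int oh, ow, gc, gn; get_dim4(gout, oh, ow, gc, gn);
  NumericVector gx(x.size()); gx.attr("dim") = x.attr("dim");
  NumericVector gw(w.size()); gw.attr("dim") = w.attr("dim");
  NumericVector gb(cout);
  if (kh == 1 && kw == 1 && sh == 1 && sw == 1 && ph == 0 && pw == 0 &&
      groups == 1) {
    arma::mat Wm(REAL(w), C, cout, false, true);
    arma::mat GW(REAL(gw), C, cout, false, true);
    arma::vec GB(REAL(gb), cout, false, true);
    R_xlen_t plane = (R_xlen_t)H * W;
    for (int n = 0; n < N; ++n) {
      arma::mat X(REAL(x) + plane * C * n, plane, C, false, true);
      arma::mat G(REAL(gout) + plane * cout * n, plane, cout, false, true);
      arma::mat GX(REAL(gx) + plane * C * n, plane, C, false, true);
      GX = G * Wm.t();
      GW += X.t() * G;
      GB += arma::sum(G, 0).t();
    }
    return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
  }
  const double* xp = REAL(x);
  const double* gp = REAL(gout);
  double* gxp = REAL(gx);
  double* gwp = REAL(gw);
  arma::mat col(kh * kw * cg, oh * ow);
  arma::mat G(coutg, oh * ow);
  for (int g = 0; g < groups; ++g) {
    arma::mat Wm = weight_mat(w, kh, kw, cg, coutg, g);
    arma::mat GW(coutg, kh * kw * cg, arma::fill::zeros);
    for (int n = 0; n < N; ++n) {
      for (int cl = 0; cl < coutg; ++cl) {
        int co = g * coutg + cl;
        const double* gcp = gp + off4(0, 0, co, n, oh, ow, cout);
        double acc = 0.0;
        for (int orow = 0; orow < oh; ++orow)
          for (int ocol = 0; ocol < ow; ++ocol) {
            double v = gcp[(R_xlen_t)orow + (R_xlen_t)oh * ocol];
            G(cl, orow * ow + ocol) = v;
            acc += v;
          }
        gb[co] += acc;
      }
      im2col(xp, H, W, C, n, g * cg, cg, kh, kw, sh, sw, ph, pw, dh, dw, oh, ow, col);
      GW += G * col.t();
      arma::mat colg = Wm.t() * G; // K x P
      col2im_add(gxp, H, W, C, n, g * cg, cg, kh, kw, sh, sw, ph, pw, dh, dw, oh, ow, colg);
    }
    for (int cl = 0; cl < coutg; ++cl) {
      int co = g * coutg + cl;
      for (int ci = 0; ci < cg; ++ci)
        for (int kr = 0; kr < kh; ++kr)
          for (int kc = 0; kc < kw; ++kc) {
            R_xlen_t woff = (R_xlen_t)kr + (R_xlen_t)kh *
              (kc + (R_xlen_t)kw * (ci + (R_xlen_t)cg * co));
            gwp[woff] += GW(cl, ci * kh * kw + kr * kw + kc);
          }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// ---------------------------------------------------------------------------
// Max-diagonal pooling (dual-branch, 2x2, parameter free)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_maxdiag_pool(NumericVector x) {
  int H, W, C, N; get_dim4(x, H, W, C, N);
  if (H % 2 != 0 || W % 2 != 0) stop("height and width must be even");
  int oh = H / 2, ow = W / 2;
  NumericVector mmap((R_xlen_t)oh * ow * C * N), dmap(mmap.size());
  IntegerVector midx(mmap.size()), didx(mmap.size());
  IntegerVector od = IntegerVector::create(oh, ow, C, N);
  mmap.attr("dim") = od; dmap.attr("dim") = od;
  midx.attr("dim") = od; didx.attr("dim") = od;
  const double* xp = REAL(x);
  double* mp = REAL(mmap); double* dp = REAL(dmap);
  int* mi = INTEGER(midx); int* di = INTEGER(didx);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = xp + off4(0, 0, c, n, H, W, C);
      for (int i = 0; i < oh; ++i)
        for (int j = 0; j < ow; ++j) {
          int r0 = 2 * i, c0 = 2 * j;
          // row-major scan; strict > keeps the first maximal cell on ties
          int br = 0, bc = 0;
          double best = xc[(R_xlen_t)r0 + (R_xlen_t)H * c0];
          for (int r = 0; r < 2; ++r)
            for (int cc = 0; cc < 2; ++cc) {
              double v = xc[(R_xlen_t)(r0 + r) + (R_xlen_t)H * (c0 + cc)];
              if (v > best) { best = v; br = r; bc = cc; }
            }
          int dr = 1 - br, dc = 1 - bc;
          R_xlen_t o = off4(i, j, c, n, oh, ow, C);
          mp[o] = best;
          dp[o] = xc[(R_xlen_t)(r0 + dr) + (R_xlen_t)H * (c0 + dc)];
          mi[o] = (r0 + br) * W + (c0 + bc);
          di[o] = (r0 + dr) * W + (c0 + dc);
        }
    }
  return List::create(_["max_map"] = mmap, _["diag_map"] = dmap,
                      _["max_idx"] = midx, _["diag_idx"] = didx);
}

// [[Rcpp::export]]
NumericVector cpp_scatter_add_plane(NumericVector gmax, NumericVector gdiag,
                                    IntegerVector midx, IntegerVector didx,
                                    int H, int W) {
  int oh, ow, C, N; get_dim4(gmax, oh, ow, C, N);
  NumericVector gx((R_xlen_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  const double* gm = REAL(gmax); const double* gd = REAL(gdiag);
  const int* mi = INTEGER(midx); const int* di = INTEGER(didx);
  double* gp = REAL(gx);
  R_xlen_t np = (R_xlen_t)oh * ow;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      R_xlen_t base = off4(0, 0, c, n, oh, ow, C);
      double* plane = gp + off4(0, 0, c, n, H, W, C);
      for (R_xlen_t k = 0; k < np; ++k) {
        int pm = mi[base + k], pd = di[base + k];
        plane[(R_xlen_t)(pm / W) + (R_xlen_t)H * (pm % W)] += gm[base + k];
        plane[(R_xlen_t)(pd / W) + (R_xlen_t)H * (pd % W)] += gd[base + k];
      }
    }
  return gx;
}

// ---------------------------------------------------------------------------
// Bilinear resize (half-pixel centers) and its adjoint
// ---------------------------------------------------------------------------

static inline void bl_coeff(int o, int I, int O, int& i0, int& i1, double& w1) {
  double s = ((double)o + 0.5) * (double)I / (double)O - 0.5;
  if (s < 0) s = 0;
  if (s > I - 1) s = I - 1;
  i0 = (int)std::floor(s);
  i1 = i0 + 1 < I ? i0 + 1 : i0;
  w1 = s - i0;
}

// [[Rcpp::export]]
NumericVector cpp_bilinear(NumericVector x, int oh, int ow) {
  int H, W, C, N; get_dim4(x, H, W, C, N);
  NumericVector out((R_xlen_t)oh * ow * C * N);
  out.attr("dim") = IntegerVector::create(oh, ow, C, N);
  std::vector<int> y0(oh), y1(oh), x0(ow), x1(ow);
  std::vector<double> wy(oh), wx(ow);
  for (int i = 0; i < oh; ++i) bl_coeff(i, H, oh, y0[i], y1[i], wy[i]);
  for (int j = 0; j < ow; ++j) bl_coeff(j, W, ow, x0[j], x1[j], wx[j]);
  const double* xp = REAL(x); double* op = REAL(out);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = xp + off4(0, 0, c, n, H, W, C);
      double* oc = op + off4(0, 0, c, n, oh, ow, C);
      for (int j = 0; j < ow; ++j)
        for (int i = 0; i < oh; ++i) {
          double a = xc[(R_xlen_t)y0[i] + (R_xlen_t)H * x0[j]];
          double b = xc[(R_xlen_t)y1[i] + (R_xlen_t)H * x0[j]];
          double cc = xc[(R_xlen_t)y0[i] + (R_xlen_t)H * x1[j]];
          double d = xc[(R_xlen_t)y1[i] + (R_xlen_t)H * x1[j]];
          double top = a * (1 - wy[i]) + b * wy[i];
          double bot = cc * (1 - wy[i]) + d * wy[i];
          oc[(R_xlen_t)i + (R_xlen_t)oh * j] = top * (1 - wx[j]) + bot * wx[j];
        }
    }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_bilinear_backward(NumericVector gout, int H, int W) {
  int oh, ow, C, N; get_dim4(gout, oh, ow, C, N);
  NumericVector gx((R_xlen_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  std::vector<int> y0(oh), y1(oh), x0(ow), x1(ow);
  std::vector<double> wy(oh), wx(ow);
  for (int i = 0; i < oh; ++i) bl_coeff(i, H, oh, y0[i], y1[i], wy[i]);
  for (int j = 0; j < ow; ++j) bl_coeff(j, W, ow, x0[j], x1[j], wx[j]);
  const double* gp = REAL(gout); double* gxp = REAL(gx);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* gc = gp + off4(0, 0, c, n, oh, ow, C);
      double* xc = gxp + off4(0, 0, c, n, H, W, C);
      for (int j = 0; j < ow; ++j)
        for (int i = 0; i < oh; ++i) {
          double g = gc[(R_xlen_t)i + (R_xlen_t)oh * j];
          xc[(R_xlen_t)y0[i] + (R_xlen_t)H * x0[j]] += g * (1 - wy[i]) * (1 - wx[j]);
          xc[(R_xlen_t)y1[i] + (R_xlen_t)H * x0[j]] += g * wy[i] * (1 - wx[j]);
          xc[(R_xlen_t)y0[i] + (R_xlen_t)H * x1[j]] += g * (1 - wy[i]) * wx[j];
          xc[(R_xlen_t)y1[i] + (R_xlen_t)H * x1[j]] += g * wy[i] * wx[j];
        }
    }
  return gx;
}

// ---------------------------------------------------------------------------
// Max-diagonal unpooling: bilinear base from the max branch, then
// one-to-one index-guided overwrite from both branches
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_maxdiag_unpool(NumericVector maxin, NumericVector diagin,
                                 IntegerVector midx, IntegerVector didx,
                                 int oh, int ow) {
  int h, w, C, N; get_dim4(maxin, h, w, C, N);
  NumericVector out = cpp_bilinear(maxin, oh, ow);
  double* op = REAL(out);
  const double* mp = REAL(maxin); const double* dp = REAL(diagin);
  const int* mi = INTEGER(midx); const int* di = INTEGER(didx);
  R_xlen_t np = (R_xlen_t)h * w;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      R_xlen_t base = off4(0, 0, c, n, h, w, C);
      double* plane = op + off4(0, 0, c, n, oh, ow, C);
      for (R_xlen_t k = 0; k < np; ++k) {
        int pm = mi[base + k], pd = di[base + k];
        if (pm < 0 || pm >= oh * ow || pd < 0 || pd >= oh * ow)
          stop("sampling index out of output bounds");
        if (pm == pd) stop("max and diagonal indices collide");
        plane[(R_xlen_t)(pm / ow) + (R_xlen_t)oh * (pm % ow)] = mp[base + k];
        plane[(R_xlen_t)(pd / ow) + (R_xlen_t)oh * (pd % ow)] = dp[base + k];
      }
    }
  return out;
}

// [[Rcpp::export]]
List cpp_maxdiag_unpool_backward(NumericVector gout, IntegerVector midx,
                                 IntegerVector didx, int h, int w) {
  int oh, ow, C, N; get_dim4(gout, oh, ow, C, N);
  NumericVector gmask = clone(gout);
  NumericVector gmax_sc((R_xlen_t)h * w * C * N), gdiag((R_xlen_t)h * w * C * N);
  IntegerVector sd = IntegerVector::create(h, w, C, N);
  gmax_sc.attr("dim") = sd; gdiag.attr("dim") = sd;
  double* gm = REAL(gmask);
  double* gms = REAL(gmax_sc); double* gds = REAL(gdiag);
  const int* mi = INTEGER(midx); const int* di = INTEGER(didx);
  R_xlen_t np = (R_xlen_t)h * w;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      R_xlen_t base = off4(0, 0, c, n, h, w, C);
      double* plane = gm + off4(0, 0, c, n, oh, ow, C);
      for (R_xlen_t k = 0; k < np; ++k) {
        int pm = mi[base + k], pd = di[base + k];
        R_xlen_t om = (R_xlen_t)(pm / ow) + (R_xlen_t)oh * (pm % ow);
        R_xlen_t od = (R_xlen_t)(pd / ow) + (R_xlen_t)oh * (pd % ow);
        gms[base + k] = plane[om];
        gds[base + k] = plane[od];
        plane[om] = 0.0; // overwritten cells do not flow through the base
        plane[od] = 0.0;
      }
    }
  NumericVector gmax = cpp_bilinear_backward(gmask, h, w);
  double* gmp = REAL(gmax);
  for (R_xlen_t k = 0; k < gmax_sc.size(); ++k) gmp[k] += gms[k];
  return List::create(_["gmax"] = gmax, _["gdiag"] = gdiag);
}

// ---------------------------------------------------------------------------
// Plain 2x2 max pooling (baseline variant) and adaptive pooling
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_maxpool2(NumericVector x) {
  int H, W, C, N; get_dim4(x, H, W, C, N);
  if (H % 2 != 0 || W % 2 != 0) stop("height and width must be even");
  int oh = H / 2, ow = W / 2;
  NumericVector out((R_xlen_t)oh * ow * C * N);
  IntegerVector idx(out.size());
  IntegerVector od = IntegerVector::create(oh, ow, C, N);
  out.attr("dim") = od; idx.attr("dim") = od;
  const double* xp = REAL(x); double* op = REAL(out); int* ip = INTEGER(idx);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = xp + off4(0, 0, c, n, H, W, C);
      for (int i = 0; i < oh; ++i)
        for (int j = 0; j < ow; ++j) {
          int r0 = 2 * i, c0 = 2 * j, br = 0, bc = 0;
          double best = xc[(R_xlen_t)r0 + (R_xlen_t)H * c0];
          for (int r = 0; r < 2; ++r)
            for (int cc = 0; cc < 2; ++cc) {
              double v = xc[(R_xlen_t)(r0 + r) + (R_xlen_t)H * (c0 + cc)];
              if (v > best) { best = v; br = r; bc = cc; }
            }
          R_xlen_t o = off4(i, j, c, n, oh, ow, C);
          op[o] = best;
          ip[o] = (r0 + br) * W + (c0 + bc);
        }
    }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_scatter_add_single(NumericVector g, IntegerVector idx,
                                     int H, int W) {
  int oh, ow, C, N; get_dim4(g, oh, ow, C, N);
  NumericVector gx((R_xlen_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  const double* gp = REAL(g); const int* ip = INTEGER(idx);
  double* xp = REAL(gx);
  R_xlen_t np = (R_xlen_t)oh * ow;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      R_xlen_t base = off4(0, 0, c, n, oh, ow, C);
      double* plane = xp + off4(0, 0, c, n, H, W, C);
      for (R_xlen_t k = 0; k < np; ++k) {
        int p = ip[base + k];
        plane[(R_xlen_t)(p / W) + (R_xlen_t)H * (p % W)] += gp[base + k];
      }
    }
  return gx;
}

// mode 0 = max (returns idx), 1 = average
// [[Rcpp::export]]
List cpp_adaptive_pool(NumericVector x, int oh, int ow, int mode) {
  int H, W, C, N; get_dim4(x, H, W, C, N);
  NumericVector out((R_xlen_t)oh * ow * C * N);
  IntegerVector idx(mode == 0 ? out.size() : 0);
  IntegerVector od = IntegerVector::create(oh, ow, C, N);
  out.attr("dim") = od;
  if (mode == 0) idx.attr("dim") = od;
  const double* xp = REAL(x); double* op = REAL(out);
  int* ip = mode == 0 ? INTEGER(idx) : nullptr;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = xp + off4(0, 0, c, n, H, W, C);
      for (int i = 0; i < oh; ++i) {
        int r0 = (int)std::floor((double)i * H / oh);
        int r1 = (int)std::ceil((double)(i + 1) * H / oh);
        for (int j = 0; j < ow; ++j) {
          int c0 = (int)std::floor((double)j * W / ow);
          int c1 = (int)std::ceil((double)(j + 1) * W / ow);
          R_xlen_t o = off4(i, j, c, n, oh, ow, C);
          if (mode == 0) {
            double best = xc[(R_xlen_t)r0 + (R_xlen_t)H * c0];
            int br = r0, bc = c0;
            for (int r = r0; r < r1; ++r)
              for (int cc = c0; cc < c1; ++cc) {
                double v = xc[(R_xlen_t)r + (R_xlen_t)H * cc];
                if (v > best) { best = v; br = r; bc = cc; }
              }
            op[o] = best;
            ip[o] = br * W + bc;
          } else {
            double acc = 0.0;
            for (int r = r0; r < r1; ++r)
              for (int cc = c0; cc < c1; ++cc)
                acc += xc[(R_xlen_t)r + (R_xlen_t)H * cc];
            op[o] = acc / ((r1 - r0) * (c1 - c0));
          }
        }
      }
    }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_adaptive_avg_backward(NumericVector gout, int H, int W) {
  int oh, ow, C, N; get_dim4(gout, oh, ow, C, N);
  NumericVector gx((R_xlen_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  const double* gp = REAL(gout); double* xp = REAL(gx);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double* xc = xp + off4(0, 0, c, n, H, W, C);
      const double* gc = gp + off4(0, 0, c, n, oh, ow, C);
      for (int i = 0; i < oh; ++i) {
        int r0 = (int)std::floor((double)i * H / oh);
        int r1 = (int)std::ceil((double)(i + 1) * H / oh);
        for (int j = 0; j < ow; ++j) {
          int c0 = (int)std::floor((double)j * W / ow);
          int c1 = (int)std::ceil((double)(j + 1) * W / ow);
          double g = gc[(R_xlen_t)i + (R_xlen_t)oh * j] / ((r1 - r0) * (c1 - c0));
          for (int r = r0; r < r1; ++r)
            for (int cc = c0; cc < c1; ++cc)
              xc[(R_xlen_t)r + (R_xlen_t)H * cc] += g;
        }
      }
    }
  return gx;
}

// ---------------------------------------------------------------------------
// Batch normalisation (per channel over H, W, N)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_bn_forward(NumericVector x, NumericVector gamma, NumericVector beta,
                    NumericVector mu, NumericVector va, double eps) {
  int H, W, C, N; get_dim4(x, H, W, C, N);
  NumericVector out(x.size()); out.attr("dim") = x.attr("dim");
  NumericVector xhat(x.size()); xhat.attr("dim") = x.attr("dim");
  const double* xp = REAL(x);
  double* op = REAL(out); double* hp = REAL(xhat);
  R_xlen_t plane = (R_xlen_t)H * W;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double m = mu[c], inv = 1.0 / std::sqrt(va[c] + eps);
      double g = gamma[c], b = beta[c];
      R_xlen_t base = off4(0, 0, c, n, H, W, C);
      for (R_xlen_t k = 0; k < plane; ++k) {
        double h = (xp[base + k] - m) * inv;
        hp[base + k] = h;
        op[base + k] = h * g + b;
      }
    }
  return List::create(_["out"] = out, _["xhat"] = xhat);
}

// [[Rcpp::export]]
List cpp_bn_stats(NumericVector x) {
  int H, W, C, N; get_dim4(x, H, W, C, N);
  NumericVector mu(C), va(C);
  const double* xp = REAL(x);
  R_xlen_t plane = (R_xlen_t)H * W;
  double nper = (double)plane * N;
  for (int c = 0; c < C; ++c) {
    double s = 0, s2 = 0;
    for (int n = 0; n < N; ++n) {
      R_xlen_t base = off4(0, 0, c, n, H, W, C);
      for (R_xlen_t k = 0; k < plane; ++k) {
        double v = xp[base + k];
        s += v; s2 += v * v;
      }
    }
    mu[c] = s / nper;
    double vv = s2 / nper - mu[c] * mu[c];
    va[c] = vv > 0 ? vv : 0;
  }
  return List::create(_["mu"] = mu, _["va"] = va);
}

// [[Rcpp::export]]
List cpp_bn_backward(NumericVector g, NumericVector xhat, NumericVector gamma,
                     NumericVector va, double eps, bool training) {
  int H, W, C, N; get_dim4(g, H, W, C, N);
  NumericVector gx(g.size()); gx.attr("dim") = g.attr("dim");
  NumericVector ggam(C), gbet(C);
  const double* gp = REAL(g); const double* hp = REAL(xhat);
  double* xp = REAL(gx);
  R_xlen_t plane = (R_xlen_t)H * W;
  double nper = (double)plane * N;
  for (int c = 0; c < C; ++c) {
    double inv = 1.0 / std::sqrt(va[c] + eps);
    double sg = 0, sgh = 0, sgam = 0, sbet = 0;
    for (int n = 0; n < N; ++n) {
      R_xlen_t base = off4(0, 0, c, n, H, W, C);
      for (R_xlen_t k = 0; k < plane; ++k) {
        double gv = gp[base + k], hv = hp[base + k];
        sgam += gv * hv; sbet += gv;
        sg += gv; sgh += gv * hv;
      }
    }
    ggam[c] = sgam; gbet[c] = sbet;
    double gam = gamma[c];
    double m1 = gam * sg / nper, m2 = gam * sgh / nper;
    for (int n = 0; n < N; ++n) {
      R_xlen_t base = off4(0, 0, c, n, H, W, C);
      if (training) {
        for (R_xlen_t k = 0; k < plane; ++k)
          xp[base + k] = inv * (gam * gp[base + k] - m1 - hp[base + k] * m2);
      } else {
        for (R_xlen_t k = 0; k < plane; ++k)
          xp[base + k] = inv * gam * gp[base + k];
      }
    }
  }
  return List::create(_["gx"] = gx, _["ggam"] = ggam, _["gbet"] = gbet);
}

// ---------------------------------------------------------------------------
// Depthwise 3x3-style convolution (groups == channels), direct loops
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_dwconv2d(NumericVector x, NumericVector w, NumericVector b,
                           int pad, int dilation) {
  int H, W, C, N; get_dim4(x, H, W, C, N);
  IntegerVector wd = w.attr("dim");
  int kh = wd[0], kw = wd[1];
  NumericVector out(x.size()); out.attr("dim") = x.attr("dim");
  const double* xp = REAL(x); const double* wp = REAL(w);
  double* op = REAL(out);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = xp + off4(0, 0, c, n, H, W, C);
      double* oc = op + off4(0, 0, c, n, H, W, C);
      const double* wc = wp + (R_xlen_t)kh * kw * c;
      double bb = b[c];
      for (int ww = 0; ww < W; ++ww)
        for (int hh = 0; hh < H; ++hh) {
          double acc = bb;
          for (int kc = 0; kc < kw; ++kc) {
            int ic = ww - pad + kc * dilation;
            if (ic < 0 || ic >= W) continue;
            for (int kr = 0; kr < kh; ++kr) {
              int ir = hh - pad + kr * dilation;
              if (ir < 0 || ir >= H) continue;
              acc += xc[(R_xlen_t)ir + (R_xlen_t)H * ic] * wc[kr + kh * kc];
            }
          }
          oc[(R_xlen_t)hh + (R_xlen_t)H * ww] = acc;
        }
    }
  return out;
}

// [[Rcpp::export]]
List cpp_dwconv2d_backward(NumericVector x, NumericVector w, NumericVector gout,
                           int pad, int dilation) {
  int H, W, C, N; get_dim4(x, H, W, C, N);
  IntegerVector wd = w.attr("dim");
  int kh = wd[0], kw = wd[1];
  NumericVector gx(x.size()); gx.attr("dim") = x.attr("dim");
  NumericVector gw(w.size()); gw.attr("dim") = w.attr("dim");
  NumericVector gb(C);
  const double* xp = REAL(x); const double* wp = REAL(w);
  const double* gp = REAL(gout);
  double* gxp = REAL(gx); double* gwp = REAL(gw);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = xp + off4(0, 0, c, n, H, W, C);
      const double* gc = gp + off4(0, 0, c, n, H, W, C);
      double* gxc = gxp + off4(0, 0, c, n, H, W, C);
      const double* wc = wp + (R_xlen_t)kh * kw * c;
      double* gwc = gwp + (R_xlen_t)kh * kw * c;
      double accb = 0;
      for (int ww = 0; ww < W; ++ww)
        for (int hh = 0; hh < H; ++hh) {
          double g = gc[(R_xlen_t)hh + (R_xlen_t)H * ww];
          accb += g;
          for (int kc = 0; kc < kw; ++kc) {
            int ic = ww - pad + kc * dilation;
            if (ic < 0 || ic >= W) continue;
            for (int kr = 0; kr < kh; ++kr) {
              int ir = hh - pad + kr * dilation;
              if (ir < 0 || ir >= H) continue;
              gxc[(R_xlen_t)ir + (R_xlen_t)H * ic] += g * wc[kr + kh * kc];
              gwc[kr + kh * kc] += g * xc[(R_xlen_t)ir + (R_xlen_t)H * ic];
            }
          }
        }
      gb[c] += accb;
    }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}
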