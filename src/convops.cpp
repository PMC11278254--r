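// Low-level primitives for the encoder-decoder network: 3x3 same-padding
// convolution via im2col + GEMM, and 2x2 max pooling. Arrays are in R's
// column-major (H, W, C, N) layout.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;


static NumericVector make4(int a, int b, int c, int d) {
  NumericVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}
static void im2col3(const double* x, int H, int W, int C, arma::mat& cols) {
  // cols: (H*W) x (9*C); patch offsets ordered dj (col) outer, di (row) inner
  cols.zeros();
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * H * W;
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di) {
        int k = (dj + 1) * 3 + (di + 1);
        double* dst = cols.colptr((size_t)k * C + c);
        for (int w = 0; w < W; ++w) {
          int ws = w + dj;
          if (ws < 0 || ws >= W) continue;
          const double* src = xc + (size_t)ws * H;
          int lo = std::max(0, -di), hi = std::min(H, H - di);
          for (int h = lo; h < hi; ++h) dst[(size_t)w * H + h] = src[h + di];
        }
      }
    }
  }
}

static void col2im3(const arma::mat& cols, int H, int W, int C, double* gx) {
  for (int c = 0; c < C; ++c) {
    double* xc = gx + (size_t)c * H * W;
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di) {
        int k = (dj + 1) * 3 + (di + 1);
        const double* src = cols.colptr((size_t)k * C + c);
        for (int w = 0; w < W; ++w) {
          int ws = w + dj;
          if (ws < 0 || ws >= W) continue;
          double* dst = xc + (size_t)ws * H;
          int lo = std::max(0, -di), hi = std::min(H, H - di);
          for (int h = lo; h < hi; ++h) dst[h + di] += src[(size_t)w * H + h];
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv_fw(NumericVector x, NumericMatrix Wm, NumericVector b) {
  IntegerVector d = x.attr("dim");
  int H = d[0], W = d[1], C = d[2], N = d[3];
  int Cout = Wm.ncol();
  arma::mat Wa(Wm.begin(), Wm.nrow(), Cout, false);
  arma::rowvec ba(b.begin(), Cout, false);
  NumericVector y = make4(H, W, Cout, N);
  arma::mat cols(H * W, 9 * C);
  for (int n = 0; n < N; ++n) {
    im2col3(x.begin() + (size_t)n * H * W * C, H, W, C, cols);
    arma::mat yn = cols * Wa;
    yn.each_row() += ba;
    std::copy(yn.begin(), yn.end(), y.begin() + (size_t)n * H * W * Cout);
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv_bw(NumericVector x, NumericMatrix Wm, NumericVector gy,
                 bool want_gx = true) {
  IntegerVector d = x.attr("dim");
  int H = d[0], W = d[1], C = d[2], N = d[3];
  int Cout = Wm.ncol();
  arma::mat Wa(Wm.begin(), Wm.nrow(), Cout, false);
  NumericVector gx = make4(H, W, C, N);
  arma::mat gW(9 * C, Cout, arma::fill::zeros);
  arma::rowvec gb(Cout, arma::fill::zeros);
  arma::mat cols(H * W, 9 * C);
  for (int n = 0; n < N; ++n) {
    arma::mat gyn(gy.begin() + (size_t)n * H * W * Cout, H * W, Cout, false);
    im2col3(x.begin() + (size_t)n * H * W * C, H, W, C, cols);
    gW += cols.t() * gyn;
    gb += arma::sum(gyn, 0);
    if (want_gx) {
      arma::mat gcols = gyn * Wa.t();
      col2im3(gcols, H, W, C, gx.begin() + (size_t)n * H * W * C);
    }
  }
  return List::create(_["gx"] = gx,
                      _["gW"] = NumericMatrix(9 * C, Cout, gW.begin()),
                      _["gb"] = NumericVector(gb.begin(), gb.end()));
}

// [[Rcpp::export]]
List cpp_maxpool_fw(NumericVector x) {
  IntegerVector d = x.attr("dim");
  int H = d[0], W = d[1], C = d[2], N = d[3];
  int Ho = H / 2, Wo = W / 2;
  NumericVector y = make4(Ho, Wo, C, N);
  IntegerVector idx(Ho * Wo * C * N);  // linear index into x of the max
  size_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + ((size_t)n * C + c) * H * W;
      size_t base = ((size_t)n * C + c) * H * W;
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h) {
          size_t i00 = (size_t)(2 * w) * H + 2 * h;
          size_t cand[4] = {i00, i00 + 1, i00 + H, i00 + H + 1};
          int best = 0;
          for (int k = 1; k < 4; ++k) if (xc[cand[k]] > xc[cand[best]]) best = k;
          y[o] = xc[cand[best]];
          idx[o] = (int)(base + cand[best]);
          ++o;
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bw(IntegerVector idx, NumericVector gy, IntegerVector xdim) {
  NumericVector gx = make4(xdim[0], xdim[1], xdim[2], xdim[3]);
  for (R_xlen_t i = 0; i < gy.size(); ++i) gx[idx[i]] += gy[i];
  return gx;
}

// batch normalisation over (H, W, N) per channel on the (H, W, C, N)
// layout; training mode computes batch statistics, otherwise the supplied
// running statistics are used
// [[Rcpp::export]]
List cpp_bn_fw(NumericVector x, NumericVector g, NumericVector be,
               NumericVector rm, NumericVector rv, bool training) {
  IntegerVector d = x.attr("dim");
  int H = d[0], W = d[1], C = d[2], N = d[3];
  size_t HW = (size_t)H * W;
  double m = (double)HW * N;
  NumericVector mu(C), va(C), isd(C);
  if (training) {
    for (int c = 0; c < C; ++c) {
      double s = 0.0, sq = 0.0;
      for (int n = 0; n < N; ++n) {
        const double* p = x.begin() + ((size_t)n * C + c) * HW;
        for (size_t k = 0; k < HW; ++k) { s += p[k]; sq += p[k] * p[k]; }
      }
      mu[c] = s / m;
      double v = sq / m - mu[c] * mu[c];
      va[c] = v > 0 ? v : 0;
    }
  } else {
    mu = clone(rm); va = clone(rv);
  }
  for (int c = 0; c < C; ++c) isd[c] = 1.0 / std::sqrt(va[c] + 1e-5);
  NumericVector y = make4(H, W, C, N), xhat = make4(H, W, C, N);
  for (int c = 0; c < C; ++c) {
    double m0 = mu[c], i0 = isd[c], g0 = g[c], b0 = be[c];
    for (int n = 0; n < N; ++n) {
      size_t off = ((size_t)n * C + c) * HW;
      const double* p = x.begin() + off;
      double* xh = xhat.begin() + off;
      double* yp = y.begin() + off;
      for (size_t k = 0; k < HW; ++k) {
        double h = (p[k] - m0) * i0;
        xh[k] = h;
        yp[k] = h * g0 + b0;
      }
    }
  }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["mu"] = mu,
                      _["va"] = va, _["isd"] = isd);
}

// [[Rcpp::export]]
List cpp_bn_bw(NumericVector gy, NumericVector xhat, NumericVector isd,
               NumericVector g) {
  IntegerVector d = gy.attr("dim");
  int H = d[0], W = d[1], C = d[2], N = d[3];
  size_t HW = (size_t)H * W;
  double m = (double)HW * N;
  NumericVector dg(C), dbe(C);
  for (int c = 0; c < C; ++c) {
    double sg = 0.0, sb = 0.0;
    for (int n = 0; n < N; ++n) {
      size_t off = ((size_t)n * C + c) * HW;
      const double* gp = gy.begin() + off;
      const double* xh = xhat.begin() + off;
      for (size_t k = 0; k < HW; ++k) { sb += gp[k]; sg += gp[k] * xh[k]; }
    }
    dg[c] = sg; dbe[c] = sb;
  }
  NumericVector gx = make4(H, W, C, N);
  for (int c = 0; c < C; ++c) {
    double coef = g[c] * isd[c], tb = dbe[c] / m, tg = dg[c] / m;
    for (int n = 0; n < N; ++n) {
      size_t off = ((size_t)n * C + c) * HW;
      const double* gp = gy.begin() + off;
      const double* xh = xhat.begin() + off;
      double* o = gx.begin() + off;
      for (size_t k = 0; k < HW; ++k)
        o[k] = (gp[k] - tb - xh[k] * tg) * coef;
    }
  }
  return List::create(_["gx"] = gx, _["dg"] = dg, _["dbe"] = dbe);
}
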