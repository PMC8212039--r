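// Low-level numerical kernels: 2-D convolution (im2col + GEMM), 2x2 max
// pooling, and the patch-based non-local means filter. All image tensors are
// H x W x C cubes in R's column-major layout; convolution weights are
// (kh, kw, Cin, Cout) arrays.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Unrolls a zero-padded cube into a (kh*kw*Cin) x (Ho*Wo) matrix. Padding is
// asymmetric (pt/pb/pl/pr) so that shifted "half-plane" convolutions can be
// expressed with the same kernel.
static arma::mat im2col(const arma::cube& x, int kh, int kw,
                        int pt, int pb, int pl, int pr) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H + pt + pb - kh + 1;
  const int Wo = W + pl + pr - kw + 1;
  arma::mat col(kh * kw * C, (arma::uword)Ho * Wo, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int b = 0; b < kw; ++b) {
      for (int a = 0; a < kh; ++a) {
        const int row = a + kh * b + kh * kw * c;
        for (int j = 0; j < Wo; ++j) {
          const int xj = j + b - pl;
          if (xj < 0 || xj >= W) continue;
          for (int i = 0; i < Ho; ++i) {
            const int xi = i + a - pt;
            if (xi < 0 || xi >= H) continue;
            col(row, (arma::uword)i + (arma::uword)Ho * j) = x(xi, xj, c);
          }
        }
      }
    }
  }
  return col;
}

// [[Rcpp::export]]
List cpp_conv_fwd(const arma::cube& x, const NumericVector& w,
                  const arma::vec& b, int pt, int pb, int pl, int pr,
                  bool want_col) {
  IntegerVector wd = w.attr("dim");
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if ((int)x.n_slices != Cin) stop("input channel count does not match kernel");
  const int Ho = x.n_rows + pt + pb - kh + 1;
  const int Wo = x.n_cols + pl + pr - kw + 1;
  if (Ho < 1 || Wo < 1) stop("kernel larger than padded input");
  const arma::mat Wm(const_cast<double*>(w.begin()),
                     (arma::uword)kh * kw * Cin, Cout, false, true);
  arma::mat col = im2col(x, kh, kw, pt, pb, pl, pr);
  arma::mat Y = col.t() * Wm;  // (Ho*Wo) x Cout
  Y.each_row() += b.t();
  arma::cube y(Y.memptr(), Ho, Wo, Cout);
  if (want_col) return List::create(_["y"] = y, _["col"] = col);
  return List::create(_["y"] = y);
}

// [[Rcpp::export]]
List cpp_conv_bwd(const arma::mat& col, const NumericVector& w,
                  const arma::cube& dy, int H, int W,
                  int pt, int pb, int pl, int pr, bool want_dx) {
  IntegerVector wd = w.attr("dim");
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  const int Ho = dy.n_rows, Wo = dy.n_cols;
  const arma::mat dYm(const_cast<double*>(dy.memptr()),
                      (arma::uword)Ho * Wo, Cout, false, true);
  arma::mat dW = col * dYm;  // (kh*kw*Cin) x Cout
  arma::vec db = arma::sum(dYm, 0).t();

  NumericVector dw(dW.memptr(), dW.memptr() + dW.n_elem);
  dw.attr("dim") = IntegerVector::create(kh, kw, Cin, Cout);

  if (!want_dx) {
    return List::create(_["dw"] = dw, _["db"] = db);
  }
  const arma::mat Wm(const_cast<double*>(w.begin()),
                     (arma::uword)kh * kw * Cin, Cout, false, true);
  arma::mat dcol = Wm * dYm.t();  // (kh*kw*Cin) x (Ho*Wo)
  arma::cube dx(H, W, Cin, arma::fill::zeros);
  for (int c = 0; c < Cin; ++c) {
    for (int b = 0; b < kw; ++b) {
      for (int a = 0; a < kh; ++a) {
        const int row = a + kh * b + kh * kw * c;
        for (int j = 0; j < Wo; ++j) {
          const int xj = j + b - pl;
          if (xj < 0 || xj >= W) continue;
          for (int i = 0; i < Ho; ++i) {
            const int xi = i + a - pt;
            if (xi < 0 || xi >= H) continue;
            dx(xi, xj, c) += dcol(row, (arma::uword)i + (arma::uword)Ho * j);
          }
        }
      }
    }
  }
  return List::create(_["dw"] = dw, _["db"] = db, _["dx"] = dx);
}

// 2x2 max pooling with stride 2; input dimensions must be even.
// [[Rcpp::export]]
List cpp_maxpool2(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  if (H % 2 || W % 2) stop("max pooling requires even spatial dimensions");
  arma::cube y(H / 2, W / 2, C);
  arma::icube idx(H / 2, W / 2, C);  // 0..3 = (di,dj) in {0,1}^2, di fastest
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < W / 2; ++j) {
      for (int i = 0; i < H / 2; ++i) {
        double best = x(2 * i, 2 * j, c);
        int code = 0;
        for (int dj = 0; dj < 2; ++dj) {
          for (int di = 0; di < 2; ++di) {
            const double v = x(2 * i + di, 2 * j + dj, c);
            if (v > best) { best = v; code = di + 2 * dj; }
          }
        }
        y(i, j, c) = best;
        idx(i, j, c) = code;
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool2_bwd(const arma::cube& dy, const arma::icube& idx) {
  const int Ho = dy.n_rows, Wo = dy.n_cols, C = dy.n_slices;
  arma::cube dx(2 * Ho, 2 * Wo, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        const int code = idx(i, j, c);
        dx(2 * i + (code % 2), 2 * j + (code / 2), c) = dy(i, j, c);
      }
  return dx;
}

static inline int reflect_idx(int v, int n) {
  // mirror without repeating the edge sample
  while (v < 0 || v >= n) {
    if (v < 0) v = -v;
    if (v >= n) v = 2 * n - 2 - v;
  }
  return v;
}

// Non-local means on a single real-valued plane. Weights are
// exp(-max(d2 - two_sig2, 0) / h2) with d2 the mean squared patch difference;
// patches are compared on a mirror-padded copy so border pixels get full
// patches.
// [[Rcpp::export]]
arma::mat cpp_nlm(const arma::mat& img, int prad, int pdist,
                  double h2, double two_sig2) {
  const int H = img.n_rows, W = img.n_cols;
  const int P = prad;
  arma::mat xp(H + 2 * P, W + 2 * P);
  for (int j = 0; j < W + 2 * P; ++j) {
    const int xj = reflect_idx(j - P, W);
    for (int i = 0; i < H + 2 * P; ++i)
      xp(i, j) = img(reflect_idx(i - P, H), xj);
  }
  const double npatch = (2.0 * P + 1) * (2.0 * P + 1);
  arma::mat out(H, W);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      double wsum = 0.0, acc = 0.0;
      for (int dj = -pdist; dj <= pdist; ++dj) {
        const int qj = j + dj;
        if (qj < 0 || qj >= W) continue;
        for (int di = -pdist; di <= pdist; ++di) {
          const int qi = i + di;
          if (qi < 0 || qi >= H) continue;
          double d2 = 0.0;
          for (int b = -P; b <= P; ++b)
            for (int a = -P; a <= P; ++a) {
              const double diff = xp(i + P + a, j + P + b) -
                                  xp(qi + P + a, qj + P + b);
              d2 += diff * diff;
            }
          d2 /= npatch;
          double arg = d2 - two_sig2;
          if (arg < 0) arg = 0;
          const double wgt = std::exp(-arg / h2);
          wsum += wgt;
          acc += wgt * img(qi, qj);
        }
      }
      out(i, j) = acc / wsum;
    }
  }
  return out;
}
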