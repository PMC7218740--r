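// Minimal conv-net primitives for the Siamese patch classifier:
// valid-mode batched 2-D convolution (im2col + GEMM) with analytic
// gradients, and 2x2 stride-2 max pooling. Array layout throughout is
// the R array layout (H, W, C, B), column-major with H fastest.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::mat im2col(const double *x, int H, int W, int C, int B,
                        int kh, int kw) {
  const int OH = H - kh + 1, OW = W - kw + 1;
  arma::mat X((arma::uword)kh * kw * C, (arma::uword)OH * OW * B);
  for (int b = 0; b < B; ++b)
    for (int ow = 0; ow < OW; ++ow)
      for (int oh = 0; oh < OH; ++oh) {
        arma::uword col = (arma::uword)b * OH * OW + (arma::uword)ow * OH + oh;
        double *dst = X.colptr(col);
        for (int c = 0; c < C; ++c)
          for (int dj = 0; dj < kw; ++dj) {
            const double *src =
                x + ((size_t)b * C + c) * H * W + (size_t)(ow + dj) * H + oh;
            for (int di = 0; di < kh; ++di)
              dst[(c * kw + dj) * kh + di] = src[di];
          }
      }
  return X;
}

// x: (H,W,C,B); w: (kh*kw*C, F) with rows ordered (di fastest, dj, c);
// bias: length F. Returns (OH,OW,F,B).
// [[Rcpp::export]]
NumericVector conv2d_forward(NumericVector x, IntegerVector xdim,
                             NumericMatrix w, NumericVector bias,
                             int kh, int kw) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], B = xdim[3];
  const int OH = H - kh + 1, OW = W - kw + 1;
  const int F = w.ncol();
  arma::mat X = im2col(REAL(x), H, W, C, B, kh, kw);
  arma::mat Wm(w.begin(), w.nrow(), w.ncol(), false);
  arma::mat Y = Wm.t() * X; // F x (OH*OW*B)
  NumericVector out((R_xlen_t)OH * OW * F * B);
  out.attr("dim") = IntegerVector::create(OH, OW, F, B);
  double *po = REAL(out);
  for (int b = 0; b < B; ++b)
    for (int f = 0; f < F; ++f) {
      const double bf = bias[f];
      for (int ow = 0; ow < OW; ++ow)
        for (int oh = 0; oh < OH; ++oh) {
          arma::uword col =
              (arma::uword)b * OH * OW + (arma::uword)ow * OH + oh;
          po[((size_t)b * F + f) * OH * OW + (size_t)ow * OH + oh] =
              Y(f, col) + bf;
        }
    }
  return out;
}

// Gradients of the valid convolution. dy: (OH,OW,F,B).
// Returns list(dw, db, dx); dx omitted (NULL) when want_dx is false.
// [[Rcpp::export]]
List conv2d_backward(NumericVector x, IntegerVector xdim, NumericMatrix w,
                     NumericVector dy, int kh, int kw, bool want_dx) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], B = xdim[3];
  const int OH = H - kh + 1, OW = W - kw + 1;
  const int F = w.ncol();
  arma::mat dY(F, (arma::uword)OH * OW * B);
  const double *pdy = REAL(dy);
  for (int b = 0; b < B; ++b)
    for (int f = 0; f < F; ++f)
      for (int ow = 0; ow < OW; ++ow)
        for (int oh = 0; oh < OH; ++oh)
          dY(f, (arma::uword)b * OH * OW + (arma::uword)ow * OH + oh) =
              pdy[((size_t)b * F + f) * OH * OW + (size_t)ow * OH + oh];

  arma::mat X = im2col(REAL(x), H, W, C, B, kh, kw);
  arma::mat dW = X * dY.t(); // (kh*kw*C, F)
  arma::vec db = arma::sum(dY, 1);

  NumericMatrix dw(w.nrow(), w.ncol());
  std::copy(dW.begin(), dW.end(), dw.begin());
  NumericVector dbv(F);
  std::copy(db.begin(), db.end(), dbv.begin());

  if (!want_dx)
    return List::create(_["dw"] = dw, _["db"] = dbv, _["dx"] = R_NilValue);

  arma::mat Wm(w.begin(), w.nrow(), w.ncol(), false);
  arma::mat dXcols = Wm * dY; // (kh*kw*C, OH*OW*B)
  NumericVector dx((R_xlen_t)H * W * C * B);
  dx.attr("dim") = xdim;
  double *pdx = REAL(dx);
  for (int b = 0; b < B; ++b)
    for (int ow = 0; ow < OW; ++ow)
      for (int oh = 0; oh < OH; ++oh) {
        arma::uword col = (arma::uword)b * OH * OW + (arma::uword)ow * OH + oh;
        const double *src = dXcols.colptr(col);
        for (int c = 0; c < C; ++c)
          for (int dj = 0; dj < kw; ++dj) {
            double *dst =
                pdx + ((size_t)b * C + c) * H * W + (size_t)(ow + dj) * H + oh;
            for (int di = 0; di < kh; ++di)
              dst[di] += src[(c * kw + dj) * kh + di];
          }
      }
  return List::create(_["dw"] = dw, _["db"] = dbv, _["dx"] = dx);
}

// 2x2 stride-2 max pooling; trailing odd row/column dropped.
// Returns list(out = (H/2,W/2,C,B), idx = 1-based argmax into x).
// [[Rcpp::export]]
List maxpool2_forward(NumericVector x, IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], B = xdim[3];
  const int OH = H / 2, OW = W / 2;
  NumericVector out((R_xlen_t)OH * OW * C * B);
  IntegerVector idx((R_xlen_t)OH * OW * C * B);
  out.attr("dim") = IntegerVector::create(OH, OW, C, B);
  idx.attr("dim") = IntegerVector::create(OH, OW, C, B);
  const double *px = REAL(x);
  double *po = REAL(out);
  int *pi = INTEGER(idx);
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      const size_t plane = ((size_t)b * C + c) * H * W;
      const size_t oplane = ((size_t)b * C + c) * OH * OW;
      for (int ow = 0; ow < OW; ++ow)
        for (int oh = 0; oh < OH; ++oh) {
          size_t best = plane + (size_t)(2 * ow) * H + 2 * oh;
          for (int dj = 0; dj < 2; ++dj)
            for (int di = 0; di < 2; ++di) {
              size_t k = plane + (size_t)(2 * ow + dj) * H + 2 * oh + di;
              if (px[k] > px[best]) best = k;
            }
          po[oplane + (size_t)ow * OH + oh] = px[best];
          pi[oplane + (size_t)ow * OH + oh] = (int)(best + 1);
        }
    }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool2_backward(NumericVector dy, IntegerVector idx,
                                IntegerVector xdim) {
  NumericVector dx((R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  dx.attr("dim") = xdim;
  double *pdx = REAL(dx);
  const double *pdy = REAL(dy);
  const int *pi = INTEGER(idx);
  const R_xlen_t n = dy.size();
  for (R_xlen_t k = 0; k < n; ++k) pdx[pi[k] - 1] += pdy[k];
  return dx;
}
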