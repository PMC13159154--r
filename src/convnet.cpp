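// Minimal convolutional building blocks for the bright-field-to-
// fluorescence translation network: 3x3 same-padding convolution
// (im2col + BLAS gemm) with its gradient, 2x2 mean pooling and nearest-
// neighbour upsampling. Layout: arma::cube (rows = y, cols = x,
// slices = channels), matching R arrays dim c(H, W, C).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat im2col3(const cube& X) {
  const uword H = X.n_rows, W = X.n_cols, C = X.n_slices;
  mat out(H * W, 9 * C, fill::zeros);
  for (uword c = 0; c < C; ++c) {
    const mat& S = X.slice(c);
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di) {
        uword col = c * 9 + (dj + 1) * 3 + (di + 1);
        double* dst = out.colptr(col);
        for (uword j = 0; j < W; ++j) {
          int js = (int)j + dj;
          if (js < 0 || js >= (int)W) continue;
          const double* src = S.colptr(js);
          uword i0 = di < 0 ? (uword)(-di) : 0;
          uword i1 = di > 0 ? H - di : H;
          for (uword i = i0; i < i1; ++i) dst[i + j * H] = src[i + di];
        }
      }
    }
  }
  return out;
}

static cube col2im3(const mat& dXcol, uword H, uword W, uword C) {
  cube dX(H, W, C, fill::zeros);
  for (uword c = 0; c < C; ++c) {
    mat& S = dX.slice(c);
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di) {
        uword col = c * 9 + (dj + 1) * 3 + (di + 1);
        const double* src = dXcol.colptr(col);
        for (uword j = 0; j < W; ++j) {
          int js = (int)j + dj;
          if (js < 0 || js >= (int)W) continue;
          double* dst = S.colptr(js);
          uword i0 = di < 0 ? (uword)(-di) : 0;
          uword i1 = di > 0 ? H - di : H;
          for (uword i = i0; i < i1; ++i) dst[i + di] += src[i + j * H];
        }
      }
    }
  }
  return dX;
}

// [[Rcpp::export]]
Rcpp::List conv3_forward(const arma::cube& X, const arma::mat& Wm,
                         const arma::vec& b, bool keep_cols) {
  mat Xcol = im2col3(X);
  mat Y = Xcol * Wm;
  Y.each_row() += b.t();
  cube Yc(Y.memptr(), X.n_rows, X.n_cols, Wm.n_cols);
  if (keep_cols)
    return Rcpp::List::create(Rcpp::Named("y") = Yc,
                              Rcpp::Named("xcol") = Xcol);
  return Rcpp::List::create(Rcpp::Named("y") = Yc);
}

// [[Rcpp::export]]
Rcpp::List conv3_backward(const arma::cube& dY, const arma::mat& Xcol,
                          const arma::mat& Wm, int Cin) {
  const uword H = dY.n_rows, Wd = dY.n_cols, F = dY.n_slices;
  mat dYm(const_cast<double*>(dY.memptr()), H * Wd, F, false, true);
  mat dW = Xcol.t() * dYm;
  vec db = sum(dYm, 0).t();
  mat dXcol = dYm * Wm.t();
  cube dX = col2im3(dXcol, H, Wd, (uword)Cin);
  return Rcpp::List::create(Rcpp::Named("dW") = dW, Rcpp::Named("db") = db,
                            Rcpp::Named("dX") = dX);
}

// [[Rcpp::export]]
arma::cube meanpool2(const arma::cube& X) {
  const uword H = X.n_rows / 2, W = X.n_cols / 2, C = X.n_slices;
  cube Y(H, W, C);
  for (uword c = 0; c < C; ++c)
    for (uword j = 0; j < W; ++j)
      for (uword i = 0; i < H; ++i)
        Y(i, j, c) = 0.25 * (X(2 * i, 2 * j, c) + X(2 * i + 1, 2 * j, c) +
                             X(2 * i, 2 * j + 1, c) + X(2 * i + 1, 2 * j + 1, c));
  return Y;
}

// [[Rcpp::export]]
arma::cube meanpool2_backward(const arma::cube& dY) {
  const uword H = dY.n_rows, W = dY.n_cols, C = dY.n_slices;
  cube dX(2 * H, 2 * W, C);
  for (uword c = 0; c < C; ++c)
    for (uword j = 0; j < W; ++j)
      for (uword i = 0; i < H; ++i) {
        double g = 0.25 * dY(i, j, c);
        dX(2 * i, 2 * j, c) = g;
        dX(2 * i + 1, 2 * j, c) = g;
        dX(2 * i, 2 * j + 1, c) = g;
        dX(2 * i + 1, 2 * j + 1, c) = g;
      }
  return dX;
}

// [[Rcpp::export]]
arma::cube upsample2(const arma::cube& X) {
  const uword H = X.n_rows, W = X.n_cols, C = X.n_slices;
  cube Y(2 * H, 2 * W, C);
  for (uword c = 0; c < C; ++c)
    for (uword j = 0; j < W; ++j)
      for (uword i = 0; i < H; ++i) {
        double v = X(i, j, c);
        Y(2 * i, 2 * j, c) = v;
        Y(2 * i + 1, 2 * j, c) = v;
        Y(2 * i, 2 * j + 1, c) = v;
        Y(2 * i + 1, 2 * j + 1, c) = v;
      }
  return Y;
}

// [[Rcpp::export]]
arma::cube upsample2_backward(const arma::cube& dY) {
  const uword H = dY.n_rows / 2, W = dY.n_cols / 2, C = dY.n_slices;
  cube dX(H, W, C);
  for (uword c = 0; c < C; ++c)
    for (uword j = 0; j < W; ++j)
      for (uword i = 0; i < H; ++i)
        dX(i, j, c) = dY(2 * i, 2 * j, c) + dY(2 * i + 1, 2 * j, c) +
                      dY(2 * i, 2 * j + 1, c) + dY(2 * i + 1, 2 * j + 1, c);
  return dX;
}
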