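// 3x3 same-padding convolution kernels for the U-Net, via im2col and
// BLAS matrix products. Arrays are column-major (H, W, N, C); patch
// matrices are (H*W*N) x (9*C) with channel fastest within each kernel
// offset, offsets enumerated row-offset-fastest.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static void im2colFill(const double* x, int H, int W, int N, int C,
                       arma::mat& X9) {
  const int P = H * W * N;
  X9.zeros(P, 9 * C);
  int k = 0;
  for (int dj = 0; dj <= 2; ++dj) {
    for (int di = 0; di <= 2; ++di, ++k) {
      for (int c = 0; c < C; ++c) {
        double* dest = X9.colptr(k * C + c);
        for (int n = 0; n < N; ++n) {
          for (int w = 0; w < W; ++w) {
            int wi = w + dj - 1;
            if (wi < 0 || wi >= W) continue;
            int h0 = std::max(0, 1 - di);        // first valid output row
            int h1 = std::min(H, H + 1 - di);    // one past last valid
            if (h1 <= h0) continue;
            const double* src =
              x + (size_t)(h0 + di - 1) + (size_t)H * (wi + (size_t)W * (n + (size_t)N * c));
            std::memcpy(dest + (size_t)h0 + (size_t)H * (w + (size_t)W * n),
                        src, (size_t)(h1 - h0) * sizeof(double));
          }
        }
      }
    }
  }
}

// weights (9, Cin, Cout) -> (9*Cin, Cout), cin fastest within offset
static arma::mat wMatrix(const double* W, int Cin, int Cout) {
  arma::mat M(9 * Cin, Cout);
  for (int o = 0; o < Cout; ++o)
    for (int c = 0; c < Cin; ++c)
      for (int k = 0; k < 9; ++k)
        M(k * Cin + c, o) = W[k + 9 * (c + (size_t)Cin * o)];
  return M;
}

// offset-flipped transpose: (9*Cout, Cin), cout fastest within offset
static arma::mat wMatrixFlip(const double* W, int Cin, int Cout) {
  arma::mat M(9 * Cout, Cin);
  for (int c = 0; c < Cin; ++c)
    for (int o = 0; o < Cout; ++o)
      for (int k = 0; k < 9; ++k)
        M(k * Cout + o, c) = W[(8 - k) + 9 * (c + (size_t)Cin * o)];
  return M;
}

// [[Rcpp::export(name = ".conv3x3Forward")]]
List conv3x3Forward(NumericVector x, IntegerVector dims, NumericVector W,
                    NumericVector b, int Cout) {
  const int H = dims[0], Wd = dims[1], N = dims[2], Cin = dims[3];
  const int P = H * Wd * N;
  NumericMatrix X9r(P, 9 * Cin);
  arma::mat X9(X9r.begin(), P, 9 * Cin, false, true);
  im2colFill(x.begin(), H, Wd, N, Cin, X9);
  arma::mat Wm = wMatrix(W.begin(), Cin, Cout);
  NumericVector yv((size_t)P * Cout);
  arma::mat Y(yv.begin(), P, Cout, false, true);
  Y = X9 * Wm;
  for (int o = 0; o < Cout; ++o) Y.col(o) += b[o];
  yv.attr("dim") = IntegerVector::create(H, Wd, N, Cout);
  return List::create(_["y"] = yv, _["X9"] = X9r);
}

// [[Rcpp::export(name = ".conv3x3Backward")]]
List conv3x3Backward(NumericMatrix X9, IntegerVector dims, NumericVector W,
                     NumericVector dy, int Cout) {
  const int H = dims[0], Wd = dims[1], N = dims[2], Cin = dims[3];
  const int P = H * Wd * N;
  arma::mat X9m(X9.begin(), X9.nrow(), X9.ncol(), false);
  arma::mat dY(dy.begin(), P, Cout, false);
  arma::mat dWm = X9m.t() * dY;                 // (9*Cin, Cout)
  NumericVector dWout(9 * Cin * Cout);
  for (int o = 0; o < Cout; ++o)
    for (int c = 0; c < Cin; ++c)
      for (int k = 0; k < 9; ++k)
        dWout[k + 9 * (c + (size_t)Cin * o)] = dWm(k * Cin + c, o);
  dWout.attr("dim") = IntegerVector::create(9, Cin, Cout);
  NumericVector db(Cout);
  for (int o = 0; o < Cout; ++o) db[o] = arma::accu(dY.col(o));

  arma::mat DY9;
  im2colFill(dy.begin(), H, Wd, N, Cout, DY9);
  NumericVector dxv((size_t)P * Cin);
  arma::mat dX(dxv.begin(), P, Cin, false, true);
  dX = DY9 * wMatrixFlip(W.begin(), Cin, Cout);
  dxv.attr("dim") = IntegerVector::create(H, Wd, N, Cin);
  return List::create(_["dx"] = dxv, _["dW"] = dWout, _["db"] = db);
}
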