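// 2x2 max pooling and nearest-neighbour upsampling kernels.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".maxPool2C")]]
List maxPool2C(NumericVector x, IntegerVector dims) {
  const int H = dims[0], W = dims[1], N = dims[2], C = dims[3];
  const int h2 = H / 2, w2 = W / 2;
  NumericVector y((size_t)h2 * w2 * N * C);
  IntegerVector arg(y.size()); // linear index into x of each max
  const double* px = x.begin();
  double* py = y.begin();
  int* pa = arg.begin();
  size_t o = 0;
  for (int c = 0; c < C; ++c)
    for (int n = 0; n < N; ++n)
      for (int w = 0; w < w2; ++w)
        for (int h = 0; h < h2; ++h, ++o) {
          size_t base = (size_t)2 * h +
            (size_t)H * (2 * w + (size_t)W * (n + (size_t)N * c));
          size_t idx[4] = {base, base + 1, base + H, base + H + 1};
          double best = px[idx[0]];
          size_t bi = idx[0];
          for (int k = 1; k < 4; ++k)
            if (px[idx[k]] > best) { best = px[idx[k]]; bi = idx[k]; }
          py[o] = best;
          pa[o] = (int)bi;
        }
  y.attr("dim") = IntegerVector::create(h2, w2, N, C);
  return List::create(_["y"] = y, _["arg"] = arg);
}

// [[Rcpp::export(name = ".maxPool2BackwardC")]]
NumericVector maxPool2BackwardC(NumericVector dy, IntegerVector arg,
                                IntegerVector dims) {
  NumericVector dx((size_t)dims[0] * dims[1] * dims[2] * dims[3]);
  const double* pd = dy.begin();
  const int* pa = arg.begin();
  double* px = dx.begin();
  for (R_xlen_t o = 0; o < dy.size(); ++o) px[pa[o]] += pd[o];
  dx.attr("dim") = dims;
  return dx;
}

// [[Rcpp::export(name = ".upsample2C")]]
NumericVector upsample2C(NumericVector x, IntegerVector dims) {
  const int H = dims[0], W = dims[1], N = dims[2], C = dims[3];
  NumericVector y((size_t)4 * H * W * N * C);
  const double* px = x.begin();
  double* py = y.begin();
  const int H2 = 2 * H;
  for (int c = 0; c < C; ++c)
    for (int n = 0; n < N; ++n)
      for (int w = 0; w < W; ++w) {
        const double* src = px + (size_t)H * (w + (size_t)W * (n + (size_t)N * c));
        double* d1 = py + (size_t)H2 * (2 * w + (size_t)(2 * W) * (n + (size_t)N * c));
        double* d2 = d1 + H2;
        for (int h = 0; h < H; ++h) {
          d1[2 * h] = d1[2 * h + 1] = src[h];
          d2[2 * h] = d2[2 * h + 1] = src[h];
        }
      }
  y.attr("dim") = IntegerVector::create(H2, 2 * W, N, C);
  return y;
}

// [[Rcpp::export(name = ".poolSumC")]]
NumericVector poolSumC(NumericVector x, IntegerVector dims) {
  const int H = dims[0], W = dims[1], N = dims[2], C = dims[3];
  const int h2 = H / 2, w2 = W / 2;
  NumericVector y((size_t)h2 * w2 * N * C);
  const double* px = x.begin();
  double* py = y.begin();
  size_t o = 0;
  for (int c = 0; c < C; ++c)
    for (int n = 0; n < N; ++n)
      for (int w = 0; w < w2; ++w)
        for (int h = 0; h < h2; ++h, ++o) {
          size_t base = (size_t)2 * h +
            (size_t)H * (2 * w + (size_t)W * (n + (size_t)N * c));
          py[o] = px[base] + px[base + 1] + px[base + H] + px[base + H + 1];
        }
  y.attr("dim") = IntegerVector::create(h2, w2, N, C);
  return y;
}
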