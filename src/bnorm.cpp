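// Batch normalization forward/backward over (P, C)-shaped activations
// (P = H*W*N voxels per channel), biased batch variance.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// [[Rcpp::export(name = ".bnForwardC")]]
List bnForwardC(NumericVector x, int P, int C, NumericVector gamma,
                NumericVector beta, NumericVector rm, NumericVector rv,
                bool training, double momentum, double eps) {
  arma::mat X(x.begin(), P, C, false);
  NumericVector yv(x.size());
  arma::mat Y(yv.begin(), P, C, false, true);
  NumericVector xhat(x.size());
  arma::mat XH(xhat.begin(), P, C, false, true);
  NumericVector mu(C), va(C), ivs(C), rmOut(C), rvOut(C);
  for (int c = 0; c < C; ++c) {
    double m, v;
    if (training) {
      m = arma::mean(X.col(c));
      v = arma::mean(arma::square(X.col(c))) - m * m;
      rmOut[c] = (1 - momentum) * rm[c] + momentum * m;
      rvOut[c] = (1 - momentum) * rv[c] + momentum * v;
    } else {
      m = rm[c]; v = rv[c];
      rmOut[c] = rm[c]; rvOut[c] = rv[c];
    }
    double is = 1.0 / std::sqrt(v + eps);
    ivs[c] = is;
    XH.col(c) = (X.col(c) - m) * is;
    Y.col(c) = XH.col(c) * gamma[c] + beta[c];
  }
  yv.attr("dim") = x.attr("dim");
  return List::create(_["y"] = yv, _["xhat"] = xhat, _["ivs"] = ivs,
                      _["rm"] = rmOut, _["rv"] = rvOut);
}

// [[Rcpp::export(name = ".bnBackwardC")]]
List bnBackwardC(NumericVector dy, NumericVector xhat, NumericVector ivs,
                 int P, int C, NumericVector gamma) {
  arma::mat DY(dy.begin(), P, C, false);
  arma::mat XH(xhat.begin(), P, C, false);
  NumericVector dxv(dy.size());
  arma::mat DX(dxv.begin(), P, C, false, true);
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    double s1 = 0, s2 = 0, dg = 0, db = 0;
    const double g = gamma[c];
    for (int p = 0; p < P; ++p) {
      const double d = DY(p, c);
      dg += d * XH(p, c);
      db += d;
    }
    s1 = db * g;
    s2 = dg * g;
    dgamma[c] = dg;
    dbeta[c] = db;
    const double is = ivs[c];
    for (int p = 0; p < P; ++p) {
      DX(p, c) = (g * DY(p, c) - s1 / P - XH(p, c) * s2 / P) * is;
    }
  }
  dxv.attr("dim") = dy.attr("dim");
  return List::create(_["dx"] = dxv, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}
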