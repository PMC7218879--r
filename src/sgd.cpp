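#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;
// One epoch of per-sample stochastic gradient descent for the
// sigmoid-sigmoid-softmax classifier. Mirrors forward()/backward()/
// apply_update() in R/network.R exactly (same visiting order, same
// max-subtraction softmax); the R path is the reference oracle the
// tests compare against. Column-major pointer arithmetic throughout:
// the Rcpp element proxies do not inline well under this toolchain.
// [[Rcpp::export]]
List cpp_sgd_epoch(NumericMatrix w_in, NumericMatrix wp_in, NumericMatrix wd_in,
          NumericMatrix X_in, IntegerVector y, IntegerVector order, double eta) {
  NumericMatrix wM = clone(w_in), wpM = clone(wp_in), wdM = clone(wd_in);
  const int N = X_in.nrow(), d = X_in.ncol();
  const int P = wM.ncol(), Q = wpM.ncol(), R = wdM.ncol();
  double *w = wM.begin(), *wp = wpM.begin(), *wd = wdM.begin(), *X = X_in.begin();
  std::vector<double> x(d+1), h(P+1), hp(Q+1), o(R), dr(R), dq(Q), dp(P);
  double gmax = 0.0;
  x[0]=1.0; h[0]=1.0; hp[0]=1.0;
  const int wr = d+1, wpr = P+1, wdr = Q+1;
  for (int oi = 0; oi < order.size(); ++oi) {
    const int i = order[oi]-1;
    for (int j = 0; j < d; ++j) x[j+1] = X[i + (size_t)N*j];
    for (int p = 0; p < P; ++p) {
      const double *col = w + (size_t)wr*p; double z = 0.0;
      for (int j = 0; j <= d; ++j) z += x[j]*col[j];
      h[p+1] = 1.0/(1.0+std::exp(-z));
    }
    for (int q = 0; q < Q; ++q) {
      const double *col = wp + (size_t)wpr*q; double z = 0.0;
      for (int p = 0; p <= P; ++p) z += h[p]*col[p];
      hp[q+1] = 1.0/(1.0+std::exp(-z));
    }
    double zmax = -INFINITY;
    for (int r = 0; r < R; ++r) {
      const double *col = wd + (size_t)wdr*r; double z = 0.0;
      for (int q = 0; q <= Q; ++q) z += hp[q]*col[q];
      o[r] = z; if (z > zmax) zmax = z;
    }
    double zsum = 0.0;
    for (int r = 0; r < R; ++r) { o[r] = std::exp(o[r]-zmax); zsum += o[r]; }
    for (int r = 0; r < R; ++r) o[r] /= zsum;
    const int t = y[i]-1;
    for (int r = 0; r < R; ++r) dr[r] = o[r] - (r==t ? 1.0 : 0.0);
    for (int q = 0; q < Q; ++q) {
      double s = 0.0;
      for (int r = 0; r < R; ++r) s += dr[r]*wd[(q+1) + (size_t)wdr*r];
      dq[q] = hp[q+1]*(1.0-hp[q+1])*s;
    }
    for (int p = 0; p < P; ++p) {
      double s = 0.0;
      const double *row = wp + (p+1);
      for (int q = 0; q < Q; ++q) s += dq[q]*row[(size_t)wpr*q];
      dp[p] = h[p+1]*(1.0-h[p+1])*s;
    }
    for (int r = 0; r < R; ++r) {
      double *col = wd + (size_t)wdr*r;
      for (int q = 0; q <= Q; ++q) {
        const double g = hp[q]*dr[r];
        if (std::fabs(g) > gmax) gmax = std::fabs(g);
        col[q] -= eta*g;
      }
    }
    for (int q = 0; q < Q; ++q) {
      double *col = wp + (size_t)wpr*q;
      for (int p = 0; p <= P; ++p) {
        const double g = h[p]*dq[q];
        if (std::fabs(g) > gmax) gmax = std::fabs(g);
        col[p] -= eta*g;
      }
    }
    for (int p = 0; p < P; ++p) {
      double *col = w + (size_t)wr*p;
      for (int j = 0; j <= d; ++j) {
        const double g = x[j]*dp[p];
        if (std::fabs(g) > gmax) gmax = std::fabs(g);
        col[j] -= eta*g;
      }
    }
  }
  return List::create(_["w"]=wM, _["w_prime"]=wpM, _["w_dprime"]=wdM, _["gmax"]=gmax);
}
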