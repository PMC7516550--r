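#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Chebyshev distance between the m-point templates starting at i and j
// (0-based), with delay tau.
static inline double cheb(const NumericVector& x, int i, int j, int m, int tau) {
  double d = 0.0;
  for (int k = 0; k < m; ++k) {
    double a = std::fabs(x[i + k * tau] - x[j + k * tau]);
    if (a > d) d = a;
  }
  return d;
}

// phi^m(r): mean over templates of log(C_i^m(r)); self-matches included.
static double apen_phi(const NumericVector& x, int m, double r, int tau) {
  int N = x.size();
  int nt = N - (m - 1) * tau;
  double acc = 0.0;
  for (int i = 0; i < nt; ++i) {
    int cnt = 0;
    for (int j = 0; j < nt; ++j) {
      if (cheb(x, i, j, m, tau) <= r) ++cnt;
    }
    acc += std::log((double)cnt / nt);
  }
  return acc / nt;
}

// [[Rcpp::export]]
double apen_cpp(NumericVector x, int m, double r, int tau) {
  return apen_phi(x, m, r, tau) - apen_phi(x, m + 1, r, tau);
}

// Counts of matching template pairs (i < j, self-matches excluded) at
// lengths m (B) and m+1 (A), over the common template range.
// [[Rcpp::export]]
NumericVector sampen_counts_cpp(NumericVector x, int m, double r, int tau) {
  int N = x.size();
  int nt = N - m * tau; // both m- and (m+1)-point templates fit
  double A = 0.0, B = 0.0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      double d = cheb(x, i, j, m, tau);
      if (d <= r) {
        ++B;
        double dm1 = std::fabs(x[i + m * tau] - x[j + m * tau]);
        if (dm1 <= r && d <= r) ++A;
      }
    }
  }
  return NumericVector::create(_["A"] = A, _["B"] = B);
}
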