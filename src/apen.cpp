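#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// phi_m(r): mean over i of log(C_i), C_i the fraction of j (self included)
// with Chebyshev distance between m-length templates <= r.
static double apen_phi(const NumericVector& x, int m, double r) {
  const int n = x.size();
  const int nv = n - m + 1;
  std::vector<int> count(nv, 1); // self-match
  for (int i = 0; i < nv; ++i) {
    for (int j = i + 1; j < nv; ++j) {
      bool within = true;
      for (int k = 0; k < m; ++k) {
        if (std::fabs(x[i + k] - x[j + k]) > r) { within = false; break; }
      }
      if (within) { ++count[i]; ++count[j]; }
    }
  }
  double acc = 0.0;
  for (int i = 0; i < nv; ++i) {
    acc += std::log(static_cast<double>(count[i]) / nv);
  }
  return acc / nv;
}

// [[Rcpp::export]]
double apen_cpp(NumericVector x, int m, double r) {
  if (x.size() < m + 2) stop("series too short for approximate entropy");
  return apen_phi(x, m, r) - apen_phi(x, m + 1, r);
}
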