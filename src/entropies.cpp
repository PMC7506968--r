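#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Chebyshev distance between templates starting at i and j (0-based),
// length m, over series y.
static inline double cheb(const double* y, int i, int j, int m) {
  double d = 0.0;
  for (int k = 0; k < m; ++k) {
    double a = std::fabs(y[i + k] - y[j + k]);
    if (a > d) d = a;
  }
  return d;
}

// Approximate entropy, classic Pincus form: N-m+1 templates, self-matches
// included, phi_m = mean(log(C_i)), ApEn = phi_m - phi_{m+1}.
// [[Rcpp::export(name = ".apen_cpp")]]
double apen_cpp(NumericVector series, int m, double r) {
  const double* y = series.begin();
  const int N = series.size();
  double phi[2];
  for (int s = 0; s < 2; ++s) {
    int mm = m + s;
    int nt = N - mm + 1;
    double acc = 0.0;
    for (int i = 0; i < nt; ++i) {
      int cnt = 0;
      for (int j = 0; j < nt; ++j)
        if (cheb(y, i, j, mm) <= r) ++cnt;
      acc += std::log((double)cnt / (double)nt);
    }
    phi[s] = acc / (double)nt;
  }
  return phi[0] - phi[1];
}

// Sample entropy pair counts: B over length-m templates, A over length-m+1,
// both with i,j in 0..N-m-1, i != j (self-matches excluded). Counting each
// unordered pair once; the ratio A/B is unaffected.
// [[Rcpp::export(name = ".sampen_counts_cpp")]]
NumericVector sampen_counts_cpp(NumericVector series, int m, double r) {
  const double* y = series.begin();
  const int N = series.size();
  const int nt = N - m;
  double A = 0.0, B = 0.0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      if (cheb(y, i, j, m) <= r) {
        B += 1.0;
        if (std::fabs(y[i + m] - y[j + m]) <= r) A += 1.0;
      }
    }
  }
  return NumericVector::create(A, B);
}

// Fuzzy entropy phi at one template length: templates of length m with
// their own mean removed, Chebyshev distance, exponential membership
// exp(-d^n / p), averaged over ordered pairs j != i with i,j in 0..nt-1.
static double fuzzy_phi(const double* y, int nt, int m,
                        double n_exp, double p) {
  std::vector<double> base(nt);
  for (int i = 0; i < nt; ++i) {
    double s = 0.0;
    for (int k = 0; k < m; ++k) s += y[i + k];
    base[i] = s / (double)m;
  }
  double acc = 0.0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double a = std::fabs((y[i + k] - base[i]) - (y[j + k] - base[j]));
        if (a > d) d = a;
      }
      acc += std::exp(-std::pow(d, n_exp) / p);
    }
  }
  // mean over ordered pairs = (2 * sum over unordered) / (nt * (nt-1))
  return 2.0 * acc / ((double)nt * (double)(nt - 1));
}

// [[Rcpp::export(name = ".fuzzyen_cpp")]]
double fuzzyen_cpp(NumericVector series, int m, double n_exp, double p) {
  const double* y = series.begin();
  const int N = series.size();
  const int nt = N - m;  // same template count for both lengths
  double phi_m  = fuzzy_phi(y, nt, m, n_exp, p);
  double phi_m1 = fuzzy_phi(y, nt, m + 1, n_exp, p);
  return std::log(phi_m) - std::log(phi_m1);
}
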