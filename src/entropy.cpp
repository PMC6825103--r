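#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Chebyshev distance between the length-m templates starting at i and j.
static inline double cheb(const double* x, int i, int j, int m) {
  double d = 0.0;
  for (int k = 0; k < m; ++k) {
    double a = std::fabs(x[i + k] - x[j + k]);
    if (a > d) d = a;
  }
  return d;
}

// Phi^k(r) of approximate entropy: mean over i of log of the fraction of
// templates (self included) within r of template i, over N-k+1 templates.
static double apen_phi(const double* x, int n, int k, double r) {
  int nt = n - k + 1;
  double acc = 0.0;
  for (int i = 0; i < nt; ++i) {
    int cnt = 0;
    for (int j = 0; j < nt; ++j) {
      if (cheb(x, i, j, k) <= r) ++cnt;
    }
    acc += std::log((double)cnt / (double)nt);
  }
  return acc / (double)nt;
}

// [[Rcpp::export(name = ".apen_cpp")]]
double apen_cpp(NumericVector x, int m, double r) {
  int n = x.size();
  const double* p = REAL(x);
  return apen_phi(p, n, m, r) - apen_phi(p, n, m + 1, r);
}

// Returns c(A, B): matched template pairs (i<j) at lengths m+1 and m,
// both over the first N-m templates, self-matches excluded.
// [[Rcpp::export(name = ".sampen_counts_cpp")]]
NumericVector sampen_counts_cpp(NumericVector x, int m, double r) {
  int n = x.size();
  const double* p = REAL(x);
  int nt = n - m; // templates usable at both lengths
  double A = 0.0, B = 0.0;
  for (int i = 0; i < nt; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      if (cheb(p, i, j, m) <= r) {
        B += 1.0;
        double a = std::fabs(p[i + m] - p[j + m]);
        if (a <= r) A += 1.0;
      }
    }
  }
  return NumericVector::create(A, B);
}

// Mean pairwise fuzzy similarity at template length k over the first nt
// templates; each template is centred on its own mean before comparison.
// Membership exp(-(d/r)^n) is dimensionless in d/r, which is what makes
// the statistic exactly invariant under affine rescaling when r tracks SD.
static double fuzz_phi(const double* x, int nt, int k, double r, double nexp) {
  std::vector<double> mu(nt);
  for (int i = 0; i < nt; ++i) {
    double s = 0.0;
    for (int q = 0; q < k; ++q) s += x[i + q];
    mu[i] = s / (double)k;
  }
  double acc = 0.0;
  for (int i = 0; i < nt; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      double d = 0.0;
      for (int q = 0; q < k; ++q) {
        double a = std::fabs((x[i + q] - mu[i]) - (x[j + q] - mu[j]));
        if (a > d) d = a;
      }
      acc += std::exp(-std::pow(d / r, nexp));
    }
  }
  // average over ordered pairs i != j equals average over unordered pairs
  return acc / ((double)nt * (nt - 1) / 2.0);
}

// [[Rcpp::export(name = ".fuzzyen_cpp")]]
double fuzzyen_cpp(NumericVector x, int m, double r, double nexp) {
  int n = x.size();
  const double* p = REAL(x);
  int nt = n - m; // same template count at both lengths
  return std::log(fuzz_phi(p, nt, m, r, nexp)) -
         std::log(fuzz_phi(p, nt, m + 1, r, nexp));
}

// Ordinal pattern census. Ties rank by order of appearance (earlier index
// lower). Returns counts over the order! patterns (Lehmer-coded).
// [[Rcpp::export(name = ".perm_counts_cpp")]]
IntegerVector perm_counts_cpp(NumericVector x, int ord, int delay) {
  int n = x.size();
  int span = (ord - 1) * delay;
  int nwin = n - span;
  int npat = 1;
  for (int k = 2; k <= ord; ++k) npat *= k;
  IntegerVector counts(npat);
  std::vector<int> rank(ord);
  const double* p = REAL(x);
  for (int t = 0; t < nwin; ++t) {
    for (int i = 0; i < ord; ++i) {
      int ri = 0;
      double xi = p[t + i * delay];
      for (int j = 0; j < ord; ++j) {
        double xj = p[t + j * delay];
        if (xj < xi || (xj == xi && j < i)) ++ri;
      }
      rank[i] = ri;
    }
    // Lehmer code of the rank permutation
    int code = 0;
    for (int i = 0; i < ord; ++i) {
      int smaller = 0;
      for (int j = i + 1; j < ord; ++j)
        if (rank[j] < rank[i]) ++smaller;
      int f = 1;
      for (int k = 2; k <= ord - 1 - i; ++k) f *= k;
      code += smaller * f;
    }
    counts[code] += 1;
  }
  return counts;
}
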