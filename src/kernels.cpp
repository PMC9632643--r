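#include <Rcpp.h>
using namespace Rcpp;

// Pairwise template-match counts for sample entropy.
// Returns counts B (length-m matches) and A (length-(m+1) matches) over all
// i < j template pairs drawn from the first n - m positions, Chebyshev
// distance, self-matches excluded by construction.
// [[Rcpp::export(name = ".sampen_counts")]]
NumericVector sampen_counts(NumericVector x, int m, double r) {
  const int n = x.size();
  const int nt = n - m; // number of templates of length m+1 (and of length m used)
  double A = 0.0, B = 0.0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      double d = 0.0;
      bool ok = true;
      for (int k = 0; k < m; ++k) {
        double dk = std::fabs(x[i + k] - x[j + k]);
        if (dk > d) d = dk;
        if (d >= r) { ok = false; break; }
      }
      if (!ok) continue;
      B += 1.0;
      double dm = std::fabs(x[i + m] - x[j + m]);
      if (std::max(d, dm) < r) A += 1.0;
    }
  }
  return NumericVector::create(_["A"] = A, _["B"] = B);
}

// Mean pairwise fuzzy similarity at embedding dimensions m and m+1 with
// locally centred embedding vectors (each vector minus its own mean) and
// membership exp(-(d/r)^p), Chebyshev distance.
// [[Rcpp::export(name = ".locfuzen_phis")]]
NumericVector locfuzen_phis(NumericVector x, int m, double r, double p) {
  const int n = x.size();
  const int nt = n - m; // templates of length m and m+1 both taken at i = 0..nt-1
  // Precompute centred vectors' prefix means.
  std::vector<double> mu_m(nt), mu_m1(nt);
  {
    double s = 0.0;
    for (int k = 0; k < m; ++k) s += x[k];
    for (int i = 0; i < nt; ++i) {
      mu_m[i] = s / m;
      if (i + 1 < nt) s += x[i + m] - x[i];
    }
    s = 0.0;
    for (int k = 0; k <= m; ++k) s += x[k];
    for (int i = 0; i < nt; ++i) {
      mu_m1[i] = s / (m + 1);
      if (i + 1 < nt) s += x[i + m + 1] - x[i];
    }
  }
  double phi_m = 0.0, phi_m1 = 0.0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double dk = std::fabs((x[i + k] - mu_m[i]) - (x[j + k] - mu_m[j]));
        if (dk > d) d = dk;
      }
      phi_m += std::exp(-std::pow(d / r, p));
      d = 0.0;
      for (int k = 0; k <= m; ++k) {
        double dk = std::fabs((x[i + k] - mu_m1[i]) - (x[j + k] - mu_m1[j]));
        if (dk > d) d = dk;
      }
      phi_m1 += std::exp(-std::pow(d / r, p));
    }
  }
  const double npairs = 0.5 * nt * (nt - 1);
  return NumericVector::create(_["phi_m"] = phi_m / npairs,
                               _["phi_m1"] = phi_m1 / npairs);
}

// LZ76 exhaustive-parsing phrase count (Lempel & Ziv 1976; Kaspar & Schuster
// 1987 scheme) of a binary symbol sequence.
// [[Rcpp::export(name = ".lz76_count")]]
int lz76_count(IntegerVector s) {
  const int n = s.size();
  if (n == 0) return 0;
  int c = 1;   // phrase count; first symbol is always a phrase
  int i = 0;   // start of current phrase search history
  int k = 1;   // length of current candidate extension
  int kmax = 1;
  int j = 1;   // start of the phrase being parsed
  while (j + k <= n) {
    if (s[i + k - 1] == s[j + k - 1]) {
      ++k;
      if (j + k > n) { ++c; break; }
    } else {
      if (k > kmax) kmax = k;
      ++i;
      if (i == j) { // no prefix reproduces the phrase: new phrase
        ++c;
        j += kmax;
        i = 0;
        k = 1;
        kmax = 1;
      } else {
        k = 1;
      }
    }
  }
  return c;
}
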