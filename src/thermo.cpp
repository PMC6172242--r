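// Partition-function machinery for the simple per-pair nucleic-acid energy
// model: inside recursion (optionally with forced-unpaired constraints),
// outside/pair-probability recursion, and minimum free energy.
//
// Grammar: nested (pseudoknot-free) sets of pairs; a pair (i,j) is allowed
// when the bases are complementary (per the energy matrix) and j-i-1 >= h
// (minimum hairpin loop). Structure energy = sum of pair energies; the empty
// structure (energy 0) is always allowed, so Z >= 1.
//
// Numerical scaling: every position consumed contributes a factor 1/sigma
// (unpaired base: w=1/sigma, pair: w(i,j)/sigma^2), so the scaled partition
// function stays O(1) and log Z = log Zhat + n log(sigma). All reported
// probabilities are ratios in which sigma cancels exactly.

#include <Rcpp.h>
using namespace Rcpp;

namespace {

// inside recursion; Z and Zb are (n x n), row i col j (0-based, i <= j).
// mask[i] true => position i forced unpaired.
void inside_fill(const IntegerVector& s, const NumericMatrix& emat, int h,
                 double rt, double sigma, const LogicalVector& mask,
                 NumericMatrix& Z, NumericMatrix& Zb) {
  const int n = s.size();
  const double inv = 1.0 / sigma;
  const double inv2 = inv * inv;
  // Zseg(i,j): scaled partition function of segment [i,j]; empty (i>j) = 1.
  auto Zseg = [&](int i, int j) -> double {
    return (i > j) ? 1.0 : Z(i, j);
  };
  for (int d = 0; d < n; ++d) {
    for (int i = 0; i + d < n; ++i) {
      const int j = i + d;
      // paired closing (i..j) with i-j pair
      double zb = 0.0;
      if (d - 1 >= h && !mask[i] && !mask[j]) {
        const double e = emat(s[i], s[j]);
        if (R_finite(e)) zb = std::exp(-e / rt) * inv2 * Zseg(i + 1, j - 1);
      }
      Zb(i, j) = zb;
      // general segment: j unpaired, or j paired with some k in [i, j-h-1]
      double z = Zseg(i, j - 1) * inv;
      for (int k = i; k <= j - h - 1; ++k) {
        if (Zb(k, j) > 0.0) z += Zseg(i, k - 1) * Zb(k, j);
      }
      Z(i, j) = z;
    }
  }
}

} // namespace

// [[Rcpp::export(name = ".pf_partition")]]
double pf_partition(IntegerVector s, NumericMatrix emat, int h, double rt,
                    double sigma, LogicalVector mask) {
  const int n = s.size();
  if (n == 0) stop("empty sequence");
  NumericMatrix Z(n, n), Zb(n, n);
  inside_fill(s, emat, h, rt, sigma, mask, Z, Zb);
  // returns log Z (unscaled)
  return std::log(Z(0, n - 1)) + n * std::log(sigma);
}

// [[Rcpp::export(name = ".pf_pairprob")]]
List pf_pairprob(IntegerVector s, NumericMatrix emat, int h, double rt,
                 double sigma) {
  const int n = s.size();
  if (n == 0) stop("empty sequence");
  LogicalVector mask(n, false);
  NumericMatrix Z(n, n), Zb(n, n);
  inside_fill(s, emat, h, rt, sigma, mask, Z, Zb);
  const double ztot = Z(0, n - 1);

  auto Zseg = [&](int i, int j) -> double {
    return (i > j) ? 1.0 : Z(i, j);
  };

  NumericMatrix P(n, n);
  // list of pairable (k,l) with Zb > 0, visited in decreasing span so that
  // every enclosing pair is finished before its interior pairs.
  for (int d = n - 1; d >= h + 1; --d) {
    for (int i = 0; i + d < n; ++i) {
      const int j = i + d;
      if (Zb(i, j) <= 0.0) continue;
      // exterior: nothing encloses (i,j)
      double out = Zseg(0, i - 1) * Zseg(j + 1, n - 1) / ztot;
      // enclosed directly by pair (k,l), k < i, l > j
      for (int k = 0; k < i; ++k) {
        for (int l = j + 1; l < n; ++l) {
          if (P(k, l) <= 0.0) continue;
          out += P(k, l) * Zseg(k + 1, i - 1) * Zseg(j + 1, l - 1) /
                 Zseg(k + 1, l - 1);
        }
      }
      double p = Zb(i, j) * out;
      if (p < 0) p = 0;
      if (p > 1) p = 1;
      P(i, j) = p;
      P(j, i) = p;
    }
  }
  const double logz = std::log(ztot) + n * std::log(sigma);
  return List::create(_["logZ"] = logz, _["pair_prob"] = P);
}

// [[Rcpp::export(name = ".pf_mfe")]]
double pf_mfe(IntegerVector s, NumericMatrix emat, int h) {
  const int n = s.size();
  if (n == 0) stop("empty sequence");
  NumericMatrix E(n, n); // 0-initialized: empty structure energy
  auto Eseg = [&](int i, int j) -> double { return (i > j) ? 0.0 : E(i, j); };
  for (int d = h + 1; d < n; ++d) {
    for (int i = 0; i + d < n; ++i) {
      const int j = i + d;
      double best = Eseg(i, j - 1); // j unpaired
      for (int k = i; k <= j - h - 1; ++k) {
        const double e = emat(s[k], s[j]);
        if (!R_finite(e)) continue;
        const double cand = Eseg(i, k - 1) + e + Eseg(k + 1, j - 1);
        if (cand < best) best = cand;
      }
      E(i, j) = best;
    }
  }
  return E(0, n - 1);
}
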