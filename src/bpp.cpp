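#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Base encoding: 1 = A, 2 = C, 3 = G, 4 = U.
// Pair energies are supplied from R (kcal/mol, negative = stabilizing) for
// AU/UA, GC/CG and GU/UG; all other juxtapositions are non-pairing.

static inline double pair_energy(int a, int b, double eAU, double eGC,
                                 double eGU) {
  if ((a == 1 && b == 4) || (a == 4 && b == 1)) return eAU;
  if ((a == 2 && b == 3) || (a == 3 && b == 2)) return eGC;
  if ((a == 3 && b == 4) || (a == 4 && b == 3)) return eGU;
  return NA_REAL;
}

// McCaskill inside/outside recursions for the equilibrium base-pair
// probability matrix under a Boltzmann ensemble of nested secondary
// structures with a minimum hairpin loop length.  Quantities are rescaled by
// a per-nucleotide factor so partition functions stay within double range
// for sequences up to a few hundred nucleotides; the scale is adapted until
// the total partition function is finite and non-zero.
//
// Inside:  Qb(i,j) = w(i,j) * Q(i+1,j-1)
//          Q(i,j)  = Q(i+1,j) + sum_k Qb(i,k) * Q(k+1,j)
// Outside: Qhat(i,j) = Q(1,i-1) Q(j+1,n)
//            + sum_{k<i<j<l} w(k,l) Qhat(k,l) Q(k+1,i-1) Q(j+1,l-1)
//          p(i,j) = Qb(i,j) * Qhat(i,j) / Q(1,n)
// [[Rcpp::export(name = ".bpp_mccaskill")]]
NumericMatrix bpp_mccaskill(IntegerVector seq, double eAU, double eGC,
                            double eGU, double RT, int min_loop) {
  const int n = seq.size();
  NumericMatrix p(n, n);
  if (n < 2) return p;

  // Boltzmann weight per admissible pair, 0 otherwise.
  std::vector<double> w(static_cast<size_t>(n) * n, 0.0);
  double wmax = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int j = i + min_loop + 1; j < n; ++j) {
      double e = pair_energy(seq[i], seq[j], eAU, eGC, eGU);
      if (!ISNA(e)) {
        double wt = std::exp(-e / RT);
        w[static_cast<size_t>(i) * n + j] = wt;
        if (wt > wmax) wmax = wt;
      }
    }
  }
  if (wmax == 0.0) return p;  // no admissible pair anywhere

  double scale = std::max(1.0, std::sqrt(wmax));
  std::vector<double> q, qb, qh;
  double qtot = 0.0;

  for (int attempt = 0; attempt < 64; ++attempt) {
    q.assign(static_cast<size_t>(n + 2) * (n + 2), 0.0);
    qb.assign(static_cast<size_t>(n + 2) * (n + 2), 0.0);
    const double s2 = scale * scale;
    // q indexed 1..n with empty segments (i > j) equal to 1.
    auto Q = [&](int i, int j) -> double {
      if (i > j) return 1.0;
      return q[static_cast<size_t>(i) * (n + 2) + j];
    };
    bool bad = false;
    for (int i = n; i >= 1 && !bad; --i) {
      for (int j = i; j <= n; ++j) {
        double wij;
        // paired-closure term (only for spans admitting a hairpin)
        double val = Q(i + 1, j) / scale;
        for (int k = i + min_loop + 1; k <= j; ++k) {
          wij = w[static_cast<size_t>(i - 1) * n + (k - 1)];
          if (wij > 0.0) {
            double b = (wij / s2) * Q(i + 1, k - 1);
            qb[static_cast<size_t>(i) * (n + 2) + k] = b;
            val += b * Q(k + 1, j);
          }
        }
        q[static_cast<size_t>(i) * (n + 2) + j] = val;
        if (!std::isfinite(val)) { bad = true; break; }
      }
    }
    qtot = Q(1, n);
    if (!bad && std::isfinite(qtot) && qtot > 0.0) break;
    if (bad || !std::isfinite(qtot)) scale *= 2.0; else scale = std::max(1.0, scale * 0.5);
  }
  if (!std::isfinite(qtot) || qtot <= 0.0)
    stop("partition function over/underflowed; sequence too long for backend");

  const double s2 = scale * scale;
  auto Q = [&](int i, int j) -> double {
    if (i > j) return 1.0;
    return q[static_cast<size_t>(i) * (n + 2) + j];
  };
  auto QB = [&](int i, int j) -> double {
    return qb[static_cast<size_t>(i) * (n + 2) + j];
  };

  // Outside pass over pairable (i,j), widest spans first so that enclosing
  // Qhat values are available.
  std::vector<std::pair<int, int> > pairs;  // 1-based
  for (int i = 1; i <= n; ++i)
    for (int j = i + min_loop + 1; j <= n; ++j)
      if (w[static_cast<size_t>(i - 1) * n + (j - 1)] > 0.0)
        pairs.push_back(std::make_pair(i, j));
  std::sort(pairs.begin(), pairs.end(),
            [](const std::pair<int, int>& a, const std::pair<int, int>& b) {
              return (a.second - a.first) > (b.second - b.first);
            });

  qh.assign(static_cast<size_t>(n + 2) * (n + 2), 0.0);
  for (size_t t = 0; t < pairs.size(); ++t) {
    const int i = pairs[t].first, j = pairs[t].second;
    double val = Q(1, i - 1) * Q(j + 1, n);
    for (size_t u = 0; u < t; ++u) {
      const int k = pairs[u].first, l = pairs[u].second;
      if (k < i && l > j) {
        double wkl = w[static_cast<size_t>(k - 1) * n + (l - 1)];
        val += (wkl / s2) * qh[static_cast<size_t>(k) * (n + 2) + l] *
               Q(k + 1, i - 1) * Q(j + 1, l - 1);
      }
    }
    qh[static_cast<size_t>(i) * (n + 2) + j] = val;
    double pij = QB(i, j) * val / qtot;
    if (pij < 0.0) pij = 0.0;
    if (pij > 1.0) pij = 1.0;
    p(i - 1, j - 1) = pij;
    p(j - 1, i - 1) = pij;
  }
  return p;
}
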