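#include <Rcpp.h>
#include <string>
#include <vector>
#include <limits>
using namespace Rcpp;

// Intermolecular duplex free energy by dynamic programming.
//
// The duplex between strands a and b (both 5'->3') is modelled as a monotone
// alignment of a against c = reverse_complement(b): an aligned column (i,k)
// pairs a[i] with the base of b that c[k] mirrors, a column is Watson-Crick
// (WC) iff a[i] == c[k]. Energy terms:
//   * one initiation term per duplex,
//   * adjacent WC columns contribute the nearest-neighbor stack dG of the
//     top-strand dinucleotide,
//   * internal (non-terminal) mismatch columns cost mm each,
//   * interior unpaired stretches (loops/bulges, g unpaired bases in total)
//     cost lopen + lext * g,
//   * terminal overhangs are free; the first and last column must be WC.
// Returns +Inf when no WC pair exists or either strand is shorter than 2 nt.
//
// States: M(i,k) = best energy of an alignment whose last column is (i,k);
// L(i,k) = best energy with the last column strictly before (i,k) and all
// bases since then unpaired (loop open, extensions paid).

static inline int base_index(char ch) {
  switch (ch) {
    case 'A': return 0;
    case 'T': return 1;
    case 'C': return 2;
    case 'G': return 3;
    default: return -1;
  }
}

static double duplex_dg_one(const std::string& a, const std::string& c,
                            const NumericMatrix& stack_dg, double init_dg,
                            double mm, double lopen, double lext) {
  const int n = a.size(), m = c.size();
  const double INF = std::numeric_limits<double>::infinity();
  if (n < 2 || m < 2) return INF;

  std::vector<int> ai(n), ci(m);
  for (int i = 0; i < n; ++i) {
    ai[i] = base_index(a[i]);
    if (ai[i] < 0) stop("invalid base '%s' in sequence", std::string(1, a[i]));
  }
  for (int k = 0; k < m; ++k) {
    ci[k] = base_index(c[k]);
    if (ci[k] < 0) stop("invalid base '%s' in sequence", std::string(1, c[k]));
  }

  std::vector<double> M((n + 1) * (m + 1), INF), L((n + 1) * (m + 1), INF);
  const int W = m + 1;
  double best = INF;

  for (int i = 1; i <= n; ++i) {
    for (int k = 1; k <= m; ++k) {
      const bool wc = ai[i - 1] == ci[k - 1];
      double prev = wc ? init_dg : INF;  // mismatches cannot open a duplex
      if (i > 1 && k > 1) {
        const double viaM = M[(i - 1) * W + (k - 1)];
        if (viaM < INF) {
          const bool prev_wc = ai[i - 2] == ci[k - 2];
          const double stack =
              (wc && prev_wc) ? stack_dg(ai[i - 2], ai[i - 1]) : 0.0;
          if (viaM + stack < prev) prev = viaM + stack;
        }
        const double viaL = L[(i - 1) * W + (k - 1)];
        if (viaL < prev) prev = viaL;
      }
      M[i * W + k] = (prev < INF) ? prev + (wc ? 0.0 : mm) : INF;
      if (wc && M[i * W + k] < best) best = M[i * W + k];

      double l = INF;
      if (i > 1) {
        if (L[(i - 1) * W + k] + lext < l) l = L[(i - 1) * W + k] + lext;
        if (M[(i - 1) * W + k] + lopen + lext < l)
          l = M[(i - 1) * W + k] + lopen + lext;
      }
      if (k > 1) {
        if (L[i * W + (k - 1)] + lext < l) l = L[i * W + (k - 1)] + lext;
        if (M[i * W + (k - 1)] + lopen + lext < l)
          l = M[i * W + (k - 1)] + lopen + lext;
      }
      L[i * W + k] = l;
    }
  }
  return best;
}

// [[Rcpp::export(name = ".duplex_dg_cpp")]]
double duplex_dg_cpp(std::string a, std::string c, NumericMatrix stack_dg,
                     double init_dg, double mm, double lopen, double lext) {
  return duplex_dg_one(a, c, stack_dg, init_dg, mm, lopen, lext);
}

// Elementwise form: dG of a[i] against its partner, where `b_rc` already
// holds the reverse complements of the physical partner strands.
// [[Rcpp::export(name = ".duplex_dg_pairs_cpp")]]
NumericVector duplex_dg_pairs_cpp(CharacterVector a, CharacterVector b_rc,
                                  NumericMatrix stack_dg, double init_dg,
                                  double mm, double lopen, double lext) {
  if (a.size() != b_rc.size()) stop("sequence vectors differ in length");
  NumericVector out(a.size());
  for (int i = 0; i < a.size(); ++i)
    out[i] = duplex_dg_one(as<std::string>(a[i]), as<std::string>(b_rc[i]),
                           stack_dg, init_dg, mm, lopen, lext);
  return out;
}

// Batch form: dG of every query against every target, where `targets_rc`
// already holds the reverse complements of the physical target strands.
// [[Rcpp::export(name = ".duplex_dg_matrix_cpp")]]
NumericMatrix duplex_dg_matrix_cpp(CharacterVector queries,
                                   CharacterVector targets_rc,
                                   NumericMatrix stack_dg, double init_dg,
                                   double mm, double lopen, double lext) {
  const int nq = queries.size(), nt = targets_rc.size();
  NumericMatrix out(nq, nt);
  std::vector<std::string> qs(nq), ts(nt);
  for (int i = 0; i < nq; ++i) qs[i] = as<std::string>(queries[i]);
  for (int j = 0; j < nt; ++j) ts[j] = as<std::string>(targets_rc[j]);
  for (int i = 0; i < nq; ++i)
    for (int j = 0; j < nt; ++j)
      out(i, j) = duplex_dg_one(qs[i], ts[j], stack_dg, init_dg, mm, lopen,
                                lext);
  return out;
}
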