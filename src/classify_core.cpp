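#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) { case 'A': return 0; case 'C': return 1; case 'G': return 2; case 'T': return 3; }
  return -1;
}

// Distinct k-mer codes (0-based, code = sum base * 4^pos, leftmost base most
// significant) of the ACGT k-mers in seq; windows containing any other
// character are skipped. Returned in order of first occurrence.
// [[Rcpp::export(name = ".distinct_kmers")]]
IntegerVector distinct_kmers(std::string seq, int k) {
  const int n = (int)seq.size();
  IntegerVector out;
  if (n < k) return out;
  std::vector<bool> seen((size_t)1 << (2 * k), false);
  std::vector<int> hits;
  hits.reserve((size_t)n);
  int code = 0, valid = 0;
  const int mask = (1 << (2 * k)) - 1;
  for (int i = 0; i < n; ++i) {
    int b = base_code(seq[(size_t)i]);
    if (b < 0) { valid = 0; code = 0; continue; }
    code = ((code << 2) | b) & mask;
    if (++valid >= k) {
      if (!seen[(size_t)code]) { seen[(size_t)code] = true; hits.push_back(code); }
    }
  }
  return wrap(hits);
}

// Naive-Bayes scoring with bootstrap. logp is the dense T x 4^k matrix of
// log P(word | taxon) with taxa in rows, so one word's taxon vector is a
// contiguous column; kmers are the read's distinct k-mer codes (0-based).
// Full-data score per taxon sums the columns of the read's distinct k-mers;
// each of n_boot draws resamples ceil(V/8) k-mers with replacement and records
// the winning taxon (first index on exact ties). Uses R's RNG (seed from R).
// [[Rcpp::export(name = ".nb_classify")]]
List nb_classify(NumericMatrix logp, IntegerVector kmers, int n_boot) {
  const int T = logp.nrow();
  const int V = kmers.size();
  const double* lp = REAL(logp);
  // gather read columns into a contiguous V x T buffer (row-major)
  std::vector<double> sub((size_t)V * (size_t)T);
  for (int v = 0; v < V; ++v) {
    const double* col = lp + (size_t)kmers[v] * T;
    std::copy(col, col + T, &sub[(size_t)v * T]);
  }
  NumericVector score(T);
  for (int v = 0; v < V; ++v) {
    const double* row = &sub[(size_t)v * T];
    for (int t = 0; t < T; ++t) score[t] += row[t];
  }
  int best = 0;
  for (int t = 1; t < T; ++t) if (score[t] > score[best]) best = t;
  bool tied = false;
  for (int t = 0; t < T; ++t)
    if (t != best && std::abs(score[t] - score[best]) < 1e-9) { tied = true; break; }

  const int draw = (V + 7) / 8;
  IntegerVector winners(n_boot);
  std::vector<double> bs((size_t)T);
  GetRNGstate();
  for (int b = 0; b < n_boot; ++b) {
    std::fill(bs.begin(), bs.end(), 0.0);
    for (int d = 0; d < draw; ++d) {
      int v = (int)(unif_rand() * V);
      if (v >= V) v = V - 1;
      const double* row = &sub[(size_t)v * T];
      for (int t = 0; t < T; ++t) bs[(size_t)t] += row[t];
    }
    int wbest = 0;
    for (int t = 1; t < T; ++t) if (bs[(size_t)t] > bs[(size_t)wbest]) wbest = t;
    winners[b] = wbest + 1; // 1-based for R
  }
  PutRNGstate();
  return List::create(_["score"] = score, _["best"] = best + 1,
                      _["tied"] = tied, _["winners"] = winners);
}
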