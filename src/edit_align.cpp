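#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// IUPAC bitmask: A=1, C=2, G=4, T=8
static inline int iupac_mask(char c) {
  switch (c) {
    case 'A': return 1;  case 'C': return 2;  case 'G': return 4;  case 'T': return 8;
    case 'R': return 1|4; case 'Y': return 2|8; case 'S': return 2|4; case 'W': return 1|8;
    case 'K': return 4|8; case 'M': return 1|2;
    case 'B': return 2|4|8; case 'D': return 1|4|8; case 'H': return 1|2|8; case 'V': return 1|2|4;
    case 'N': return 15;
    default: return -1;
  }
}

static inline int base_mask(char c) {
  switch (c) {
    case 'A': return 1; case 'C': return 2; case 'G': return 4; case 'T': return 8;
    default: return 0; // N or anything else in the read never matches at zero cost
  }
}

// Semi-global alignment of a full IUPAC primer against a window of the read:
// the primer must be consumed entirely, the read end-points are free within
// the window. Unit-cost edits; an IUPAC code matches any base of its set at
// zero cost. Returns c(dist, start, end) in window-local 0-based half-open
// coordinates, or c(-1, 0, 0) when the minimal distance exceeds max_err.
// Tie-break: minimal distance, then smaller start, then shorter span (smaller
// end). Starts are propagated through the DP taking the minimum over all
// optimal predecessors so the reported start is the smallest achievable.
// [[Rcpp::export(name = ".semi_global_match")]]
IntegerVector semi_global_match(std::string window, std::string primer, int max_err) {
  const int p = (int)primer.size(), w = (int)window.size();
  std::vector<int> pm(p);
  for (int i = 0; i < p; ++i) {
    int m = iupac_mask(primer[(size_t)i]);
    if (m < 0) stop("invalid IUPAC character '%s' in primer", std::string(1, primer[(size_t)i]));
    pm[(size_t)i] = m;
  }
  std::vector<int> rm(w);
  for (int j = 0; j < w; ++j) rm[(size_t)j] = base_mask(window[(size_t)j]);

  // D[i][j]: min edits aligning primer[0..i) to some suffix of window[0..j)
  // S[i][j]: smallest start of an optimal such alignment
  std::vector<int> Dprev(w + 1), Dcur(w + 1), Sprev(w + 1), Scur(w + 1);
  for (int j = 0; j <= w; ++j) { Dprev[(size_t)j] = 0; Sprev[(size_t)j] = j; }
  for (int i = 1; i <= p; ++i) {
    Dcur[0] = i; Scur[0] = 0;
    for (int j = 1; j <= w; ++j) {
      int sub = Dprev[(size_t)(j - 1)] + ((pm[(size_t)(i - 1)] & rm[(size_t)(j - 1)]) ? 0 : 1);
      int del = Dprev[(size_t)j] + 1;      // consume primer base, not read
      int ins = Dcur[(size_t)(j - 1)] + 1; // consume read base, not primer
      int best = sub, st = Sprev[(size_t)(j - 1)];
      if (del < best) { best = del; st = Sprev[(size_t)j]; }
      else if (del == best && Sprev[(size_t)j] < st) st = Sprev[(size_t)j];
      if (ins < best) { best = ins; st = Scur[(size_t)(j - 1)]; }
      else if (ins == best && Scur[(size_t)(j - 1)] < st) st = Scur[(size_t)(j - 1)];
      Dcur[(size_t)j] = best; Scur[(size_t)j] = st;
    }
    std::swap(Dprev, Dcur); std::swap(Sprev, Scur);
  }

  int bd = max_err + 1, bs = 0, be = 0;
  for (int j = 0; j <= w; ++j) {
    int d = Dprev[(size_t)j], s = Sprev[(size_t)j];
    if (d > max_err) continue;
    bool better = d < bd || (d == bd && (s < bs || (s == bs && j < be)));
    if (better) { bd = d; bs = s; be = j; }
  }
  if (bd > max_err) return IntegerVector::create(-1, 0, 0);
  return IntegerVector::create(bd, bs, be);
}
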