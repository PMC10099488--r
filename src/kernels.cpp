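#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Mismatches between two C strings compared gaplessly from position 0 over
// the shorter length. Returns -1 early if the count exceeds `cap` (cap < 0
// disables the early exit).
static inline int mismatch_count(const char* a, int la, const char* b, int lb,
                                 int cap) {
  int n = la < lb ? la : lb;
  int mm = 0;
  for (int i = 0; i < n; ++i) {
    if (a[i] != b[i]) {
      ++mm;
      if (cap >= 0 && mm > cap) return -1;
    }
  }
  return mm;
}

// Greedy centroid clustering. `seqs` must already be sorted by the caller's
// deterministic rule (abundance desc, then lexicographic). A sequence joins
// the first centroid with identity >= `identity`; otherwise it founds a new
// centroid. Identity = matching positions in the gapless overlap divided by
// the length of the LONGER sequence (length differences penalised).
// Returns 1-based centroid index per sequence.
// [[Rcpp::export(name = ".greedy_cluster_cpp")]]
IntegerVector greedy_cluster_cpp(CharacterVector seqs, double identity) {
  int n = seqs.size();
  IntegerVector out(n);
  std::vector<const char*> cent;
  std::vector<int> cent_len;
  for (int i = 0; i < n; ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    int ls = (int) std::strlen(s);
    int hit = -1;
    for (size_t c = 0; c < cent.size(); ++c) {
      int lc = cent_len[c];
      int longer = ls > lc ? ls : lc;
      // max mismatches (on the overlap) still compatible with `identity`
      int shorter = ls < lc ? ls : lc;
      int cap = (int) std::floor((1.0 - identity) * longer + 1e-9) -
                (longer - shorter);
      if (cap < 0) continue;
      int mm = mismatch_count(s, ls, cent[c], lc, cap);
      if (mm >= 0) {
        double ident = (double)(shorter - mm) / (double) longer;
        if (ident >= identity - 1e-12) { hit = (int) c; break; }
      }
    }
    if (hit < 0) {
      cent.push_back(s);
      cent_len.push_back(ls);
      hit = (int) cent.size() - 1;
    }
    out[i] = hit + 1;
  }
  return out;
}

// Best gapless assignment of each read to a reference locus.
// `hint` (1-based, NA allowed) is an optional per-read candidate — e.g. from
// an exact prefix-hash lookup — evaluated first so that the scan over the
// remaining loci can stop as soon as a locus is provably worse than both the
// best hit and a potential tie. Runner-up counts are therefore only exact up
// to best+1, which is all that unique-assignment needs.
// Columns: best locus (1-based, NA if none), best mismatches, runner-up
// mismatches (possibly truncated, NA if single locus).
// [[Rcpp::export(name = ".assign_reads_cpp")]]
IntegerMatrix assign_reads_cpp(CharacterVector reads, CharacterVector refs,
                               IntegerVector hint) {
  int n = reads.size(), m = refs.size();
  std::vector<const char*> rf(m);
  std::vector<int> rl(m);
  for (int j = 0; j < m; ++j) {
    rf[j] = CHAR(STRING_ELT(refs, j));
    rl[j] = (int) std::strlen(rf[j]);
  }
  bool use_hint = hint.size() == n;
  IntegerMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    const char* s = CHAR(STRING_ELT(reads, i));
    int ls = (int) std::strlen(s);
    int best = NA_INTEGER, b1 = INT_MAX, b2 = INT_MAX;
    int h = (use_hint && hint[i] != NA_INTEGER) ? hint[i] - 1 : -1;
    if (h >= 0 && h < m) {
      b1 = mismatch_count(s, ls, rf[h], rl[h], -1);
      best = h + 1;
    }
    for (int j = 0; j < m; ++j) {
      if (j == h) continue;
      int cap;
      if (b1 == INT_MAX) cap = -1;
      else {
        cap = (b2 < b1 + 1) ? b2 : b1 + 1; // enough to resolve ties
      }
      int mm = mismatch_count(s, ls, rf[j], rl[j], cap);
      if (mm < 0) continue;
      if (mm < b1) { b2 = b1; b1 = mm; best = j + 1; }
      else if (mm < b2) { b2 = mm; }
    }
    out(i, 0) = (b1 == INT_MAX) ? NA_INTEGER : best;
    out(i, 1) = (b1 == INT_MAX) ? NA_INTEGER : b1;
    out(i, 2) = (b2 == INT_MAX) ? NA_INTEGER : b2;
  }
  return out;
}

// Per-column base counts for a stack of equal-start (gapless) sequences.
// Rows: A, C, G, T, N/other; columns 1..max length.
// [[Rcpp::export(name = ".base_counts_cpp")]]
IntegerMatrix base_counts_cpp(CharacterVector seqs) {
  int n = seqs.size();
  int L = 0;
  for (int i = 0; i < n; ++i) {
    int l = (int) std::strlen(CHAR(STRING_ELT(seqs, i)));
    if (l > L) L = l;
  }
  IntegerMatrix out(5, L);
  for (int i = 0; i < n; ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    int l = (int) std::strlen(s);
    for (int j = 0; j < l; ++j) {
      int r;
      switch (s[j]) {
        case 'A': case 'a': r = 0; break;
        case 'C': case 'c': r = 1; break;
        case 'G': case 'g': r = 2; break;
        case 'T': case 't': r = 3; break;
        default: r = 4;
      }
      out(r, j) += 1;
    }
  }
  return out;
}
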