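#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Maximum number of matching positions over all gap-free alignments of a
// against b: every relative offset with at least one overlapping position is
// considered, with no end-anchoring.
// [[Rcpp::export]]
int cpp_max_gapfree_matches(const std::string& a, const std::string& b) {
  const int na = (int) a.size(), nb = (int) b.size();
  if (na == 0 || nb == 0) stop("empty sequence in gap-free match counting");
  int best = 0;
  for (int off = -(nb - 1); off <= na - 1; ++off) {
    const int lo = std::max(0, off);
    const int hi = std::min(na, off + nb);
    int cnt = 0;
    for (int i = lo; i < hi; ++i)
      if (a[i] == b[i - off]) ++cnt;
    if (cnt > best) best = cnt;
  }
  return best;
}

// Seed-anchored matching: windows of |primer| over seq where the 3'-terminal
// seed_len bases match exactly and the remaining 5' bases carry at most
// max_mm mismatches. Characters are compared literally, so any non-ACGT
// reference letter counts as a mismatch (and breaks the seed). Returns a
// two-column matrix (start, mismatches), 1-based starts.
// [[Rcpp::export]]
IntegerMatrix cpp_find_sites(const std::string& primer, const std::string& seq,
                             int seed_len, int max_mm) {
  const int m = (int) primer.size(), L = (int) seq.size();
  std::vector<int> starts, mms;
  for (int s = 0; s + m <= L; ++s) {
    bool seed_ok = true;
    for (int k = m - seed_len; k < m; ++k)
      if (primer[k] != seq[s + k]) { seed_ok = false; break; }
    if (!seed_ok) continue;
    int mm = 0;
    for (int k = 0; k < m - seed_len; ++k) {
      if (primer[k] != seq[s + k]) {
        if (++mm > max_mm) break;
      }
    }
    if (mm <= max_mm) { starts.push_back(s + 1); mms.push_back(mm); }
  }
  IntegerMatrix out((int) starts.size(), 2);
  for (int i = 0; i < (int) starts.size(); ++i) {
    out(i, 0) = starts[i];
    out(i, 1) = mms[i];
  }
  colnames(out) = CharacterVector::create("start", "mismatches");
  return out;
}

// One call per (primer, orientation) over a whole reference set.
// [[Rcpp::export]]
List cpp_find_sites_batch(const std::string& primer, CharacterVector seqs,
                          int seed_len, int max_mm) {
  const int n = seqs.size();
  List out(n);
  for (int i = 0; i < n; ++i)
    out[i] = cpp_find_sites(primer, std::string(seqs[i]), seed_len, max_mm);
  return out;
}

// Shortest valid amplicon per sequence for one (forward, reverse) primer
// combination. fstarts/rstarts are lists (one element per sequence) of
// 1-based sense-strand start positions of forward and reverse-binding
// sites; flen/rlen the primer lengths. A pairing is valid when the reverse
// site starts strictly downstream of the forward site end; the product
// spans both primer footprints. NA when no valid pairing exists.
// [[Rcpp::export]]
NumericVector cpp_shortest_amplicons(List fstarts, int flen, List rstarts, int rlen) {
  const int n = fstarts.size();
  NumericVector out(n, NA_REAL);
  for (int i = 0; i < n; ++i) {
    IntegerVector fs = fstarts[i];
    IntegerVector rs = rstarts[i];
    if (fs.size() == 0 || rs.size() == 0) continue;
    double best = R_PosInf;
    for (int a = 0; a < fs.size(); ++a) {
      const int fend = fs[a] + flen - 1;
      // smallest reverse start strictly downstream minimizes the product
      int rmin = INT_MAX;
      for (int b = 0; b < rs.size(); ++b)
        if (rs[b] > fend && rs[b] < rmin) rmin = rs[b];
      if (rmin == INT_MAX) continue;
      const double len = (double) (rmin + rlen - 1) - fs[a] + 1;
      if (len < best) best = len;
    }
    if (best < R_PosInf) out[i] = best;
  }
  return out;
}

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    default:  return 'N';
  }
}

// Hairpin screen: fold the reverse complement of the 3'-terminal seed back
// onto the primer, gap-free, at every full-window offset that does not
// overlap the seed's own source positions. A hit requires the primer's last
// base to pair and at least min_match of the seed_len - 1 preceding bases.
// [[Rcpp::export]]
bool cpp_hairpin_hit(const std::string& p, int seed_len, int min_match) {
  const int n = (int) p.size();
  if (n < 2 * seed_len) stop("primer too short for hairpin screen");
  std::string f(seed_len, 'N');
  for (int k = 0; k < seed_len; ++k) f[k] = comp_base(p[n - 1 - k]);
  // window [j, j + seed_len - 1] must lie entirely before the seed source
  for (int j = 0; j + seed_len <= n - seed_len; ++j) {
    if (f[0] != p[j]) continue;  // terminal base must pair
    int cnt = 0;
    for (int k = 1; k < seed_len; ++k)
      if (f[k] == p[j + k]) ++cnt;
    if (cnt >= min_match) return true;
  }
  return false;
}
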