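// Affine-gap global alignment (Gotoh) with traceback, used for pairwise
// percent identity between clone sequences. Identity is computed as
// matching columns / alignment columns, excluding any leading or trailing
// run of columns in which either sequence is gapped (clone ends are ragged
// after ORF trimming, so end gaps carry no signal).
//
// Gap convention: a gap run of length k costs open + k * extend, matching
// the convention of the Bioconductor aligner so the two can be compared
// head to head in tests.

#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>

using namespace Rcpp;

namespace {

const double NEG_INF = -std::numeric_limits<double>::infinity();

struct AlignResult {
  double score;
  double identity;
  int columns;   // columns kept after end-gap exclusion
};

inline double subst_score(char a, char b, double match, double mismatch) {
  if (a == 'N' || b == 'N') return 0.0;  // ambiguous base: neutral
  return (a == b) ? match : mismatch;
}

AlignResult align_pair(const std::string& a, const std::string& b,
                       double match, double mismatch,
                       double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  const double gi = -(gap_open + gap_extend);  // open a new gap
  const double ge = -gap_extend;               // extend an existing gap

  // state 0 = M (diagonal), 1 = X (gap in b, consume a), 2 = Y (gap in a).
  // Scores use two rolling rows; the traceback packs the predecessor state
  // of M/X/Y into one byte per cell (2 bits each), keeping the working set
  // cache-resident.
  std::vector<double> Mp(m + 1, NEG_INF), Xp(m + 1, NEG_INF),
      Yp(m + 1, NEG_INF);
  std::vector<double> Mc(m + 1), Xc(m + 1), Yc(m + 1);
  std::vector<unsigned char> tb(static_cast<size_t>(n + 1) * (m + 1), 0);

  Mp[0] = 0.0;
  for (int j = 1; j <= m; ++j) {
    Yp[j] = -(gap_open + gap_extend * j);
  }

  for (int i = 1; i <= n; ++i) {
    Mc[0] = NEG_INF;
    Yc[0] = NEG_INF;
    Xc[0] = -(gap_open + gap_extend * i);
    unsigned char* tbrow = &tb[static_cast<size_t>(i) * (m + 1)];
    const char ai = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      const double s = subst_score(ai, b[j - 1], match, mismatch);
      unsigned char cell = 0;
      // M from diagonal of previous row
      double best = Mp[j - 1];
      if (Xp[j - 1] > best) { best = Xp[j - 1]; cell |= 1; }
      if (Yp[j - 1] > best) { best = Yp[j - 1]; cell = (cell & ~3u) | 2; }
      Mc[j] = best + s;
      // X: gap in b (consume a), from previous row same column
      best = Mp[j] + gi;
      unsigned char arg = 0;
      if (Xp[j] + ge > best) { best = Xp[j] + ge; arg = 1; }
      if (Yp[j] + gi > best) { best = Yp[j] + gi; arg = 2; }
      Xc[j] = best;
      cell |= arg << 2;
      // Y: gap in a (consume b), from current row previous column
      // (args store state numbers: 0 = M, 1 = X, 2 = Y)
      best = Mc[j - 1] + gi;
      arg = 0;
      if (Yc[j - 1] + ge > best) { best = Yc[j - 1] + ge; arg = 2; }
      if (Xc[j - 1] + gi > best) { best = Xc[j - 1] + gi; arg = 1; }
      Yc[j] = best;
      cell |= arg << 4;
      tbrow[j] = cell;
    }
    Mp.swap(Mc); Xp.swap(Xc); Yp.swap(Yc);
  }

  double score = Mp[m];
  int state = 0;
  if (Xp[m] > score) { score = Xp[m]; state = 1; }
  if (Yp[m] > score) { score = Yp[m]; state = 2; }

  // traceback: record per column whether it is a match, mismatch or gap
  // (0 = aligned match, 1 = aligned mismatch, 2 = gap column)
  std::vector<unsigned char> cols;
  cols.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (i == 0) {            // only b left: gap columns in a
      cols.push_back(2);
      --j;
    } else if (j == 0) {     // only a left: gap columns in b
      cols.push_back(2);
      --i;
    } else {
      const unsigned char cell = tb[static_cast<size_t>(i) * (m + 1) + j];
      if (state == 0) {
        bool is_match = (a[i - 1] == b[j - 1]) &&
                        (a[i - 1] != 'N') && (b[j - 1] != 'N');
        cols.push_back(is_match ? 0 : 1);
        --i; --j;
        state = cell & 3;
      } else if (state == 1) {
        cols.push_back(2);
        --i;
        state = (cell >> 2) & 3;
      } else {
        cols.push_back(2);
        --j;
        state = (cell >> 4) & 3;
      }
    }
  }
  // cols is reversed; find kept window excluding end-gap runs on both ends
  int L = cols.size();
  int from = 0, to = L - 1;
  while (from < L && cols[L - 1 - from] == 2) ++from;   // leading (reversed)
  while (to >= 0 && cols[L - 1 - to] == 2) --to;
  // NOTE: cols[k] corresponds to column L-1-k of the alignment
  int kept = 0, matches = 0;
  for (int k = from; k <= to; ++k) {
    ++kept;
    if (cols[L - 1 - k] == 0) ++matches;
  }
  AlignResult res;
  res.score = score;
  res.identity = kept > 0 ? static_cast<double>(matches) / kept : 0.0;
  res.columns = kept;
  return res;
}

}  // namespace

// [[Rcpp::export(name = ".nw_align")]]
List nw_align(std::string a, std::string b, double match, double mismatch,
              double gap_open, double gap_extend) {
  AlignResult r = align_pair(a, b, match, mismatch, gap_open, gap_extend);
  return List::create(_["score"] = r.score,
                      _["identity"] = r.identity,
                      _["columns"] = r.columns);
}

// [[Rcpp::export(name = ".nw_identity_many")]]
NumericVector nw_identity_many(std::string query, CharacterVector refs,
                               double match, double mismatch,
                               double gap_open, double gap_extend) {
  const int k = refs.size();
  NumericVector out(k);
  for (int t = 0; t < k; ++t) {
    std::string r = as<std::string>(refs[t]);
    if (r == query) {
      out[t] = 1.0;
    } else {
      out[t] = align_pair(r, query, match, mismatch,
                          gap_open, gap_extend).identity;
    }
  }
  return out;
}
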