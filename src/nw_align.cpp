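#include <Rcpp.h>
#include <vector>
#include <string>

using namespace Rcpp;

// Optimal global (Needleman-Wunsch) alignment with linear gap penalty.
//
// Scoring: +match for an identical A/C/G/T pair, +mismatch for a differing
// pair, +gap per gap column. A column in which either base is ambiguous
// (anything outside A/C/G/T, e.g. N) scores 0 and is counted as neither a
// match nor a mismatch, but still occupies an alignment column.
//
// Traceback preference on score ties is diagonal > up (gap in query) >
// left (gap in reference), which makes the reported match/column counts
// deterministic among co-optimal alignments.

static inline bool is_acgt(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

struct NwResult {
  double score;
  int matches;
  int columns;
};

static inline int encode_base(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default: return 4;  // N and any other ambiguity code
  }
}

static NwResult nw_core(const std::string &q, const std::string &r,
                        double match, double mismatch, double gap) {
  const int m = q.size(), n = r.size();
  std::vector<signed char> qe(m), re(n);
  for (int i = 0; i < m; ++i) qe[i] = encode_base(q[i]);
  for (int j = 0; j < n; ++j) re[j] = encode_base(r[j]);
  // 5x5 substitution table; any pair involving an ambiguous base scores 0
  double sub_tab[25];
  for (int a = 0; a < 5; ++a)
    for (int b = 0; b < 5; ++b)
      sub_tab[a * 5 + b] = (a == 4 || b == 4) ? 0.0
                           : (a == b ? match : mismatch);

  std::vector<double> prev(n + 1), cur(n + 1);
  std::vector<unsigned char> tb((size_t)(m + 1) * (n + 1), 2);
  for (int j = 0; j <= n; ++j) prev[j] = gap * j;
  for (int i = 0; i <= m; ++i) tb[(size_t)i * (n + 1)] = 1;
  tb[0] = 0;

  for (int i = 1; i <= m; ++i) {
    cur[0] = gap * i;
    const double *qrow = sub_tab + 5 * qe[i - 1];
    unsigned char *tbrow = tb.data() + (size_t)i * (n + 1);
    for (int j = 1; j <= n; ++j) {
      const double d = prev[j - 1] + qrow[re[j - 1]];
      const double u = prev[j] + gap;
      const double l = cur[j - 1] + gap;
      double best = d;
      unsigned char dir = 0;
      if (u > best) { best = u; dir = 1; }
      if (l > best) { best = l; dir = 2; }
      cur[j] = best;
      tbrow[j] = dir;
    }
    std::swap(prev, cur);
  }

  NwResult out;
  out.score = prev[n];
  out.matches = 0;
  out.columns = 0;
  int i = m, j = n;
  while (i > 0 || j > 0) {
    unsigned char dir = tb[(size_t)i * (n + 1) + j];
    if (i > 0 && j > 0 && dir == 0) {
      if (q[i - 1] == r[j - 1] && is_acgt(q[i - 1])) out.matches++;
      --i; --j;
    } else if (i > 0 && (dir == 1 || j == 0)) {
      --i;
    } else {
      --j;
    }
    out.columns++;
  }
  return out;
}

// [[Rcpp::export(name = ".nw_align_one")]]
NumericVector nw_align_one(std::string query, std::string ref,
                           double match, double mismatch, double gap) {
  NwResult res = nw_core(query, ref, match, mismatch, gap);
  return NumericVector::create(_["score"] = res.score,
                               _["matches"] = (double)res.matches,
                               _["aligned_columns"] = (double)res.columns);
}

// [[Rcpp::export(name = ".nw_align_many")]]
NumericMatrix nw_align_many(std::string query, CharacterVector refs,
                            double match, double mismatch, double gap) {
  const int k = refs.size();
  NumericMatrix out(k, 3);
  colnames(out) = CharacterVector::create("score", "matches", "aligned_columns");
  for (int i = 0; i < k; ++i) {
    std::string r = as<std::string>(refs[i]);
    NwResult res = nw_core(query, r, match, mismatch, gap);
    out(i, 0) = res.score;
    out(i, 1) = res.matches;
    out(i, 2) = res.columns;
  }
  return out;
}
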