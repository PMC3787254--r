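#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// IUPAC bitmasks: A=1 C=2 G=4 T=8 (U folded to T upstream).
static int iupac_table[256];
static bool iupac_init_done = false;

static void iupac_init() {
  if (iupac_init_done) return;
  for (int i = 0; i < 256; ++i) iupac_table[i] = 0;
  iupac_table[(int)'A'] = 1;  iupac_table[(int)'C'] = 2;
  iupac_table[(int)'G'] = 4;  iupac_table[(int)'T'] = 8;
  iupac_table[(int)'U'] = 8;
  iupac_table[(int)'R'] = 5;  iupac_table[(int)'Y'] = 10;
  iupac_table[(int)'S'] = 6;  iupac_table[(int)'W'] = 9;
  iupac_table[(int)'K'] = 12; iupac_table[(int)'M'] = 3;
  iupac_table[(int)'B'] = 14; iupac_table[(int)'D'] = 13;
  iupac_table[(int)'H'] = 11; iupac_table[(int)'V'] = 7;
  iupac_table[(int)'N'] = 15;
  iupac_init_done = true;
}

static inline int bits_of(char c) { return iupac_table[(unsigned char)c]; }

// Global Needleman-Wunsch: match +1, mismatch -1, gap -2 (linear).
// Traceback tie-break: diagonal, then gap-in-read (consume b), then
// gap-in-ref (consume a). Gap placement is canonicalized 3'-most in R.
// [[Rcpp::export]]
List cpp_nw_align(std::string a, std::string b) {
  const int n = a.size(), m = b.size();
  const int GAP = -2, MATCH = 1, MISMATCH = -1;
  std::vector<int> prev(m + 1), cur(m + 1);
  // traceback: 0 = diag, 1 = left (gap in a), 2 = up (gap in b)
  std::vector<unsigned char> tb((size_t)(n + 1) * (m + 1));
  for (int j = 0; j <= m; ++j) { prev[j] = GAP * j; tb[j] = 1; }
  tb[0] = 0;
  for (int i = 1; i <= n; ++i) {
    cur[0] = GAP * i;
    tb[(size_t)i * (m + 1)] = 2;
    for (int j = 1; j <= m; ++j) {
      int s = (a[i - 1] == b[j - 1]) ? MATCH : MISMATCH;
      int d = prev[j - 1] + s;
      int l = cur[j - 1] + GAP;
      int u = prev[j] + GAP;
      int best = d; unsigned char mv = 0;
      if (l > best) { best = l; mv = 1; }
      if (u > best) { best = u; mv = 2; }
      cur[j] = best;
      tb[(size_t)i * (m + 1) + j] = mv;
    }
    std::swap(prev, cur);
  }
  int score = prev[m];
  std::string aa, ab;
  aa.reserve(n + m); ab.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    unsigned char mv = tb[(size_t)i * (m + 1) + j];
    if (i > 0 && j > 0 && mv == 0) {
      aa.push_back(a[i - 1]); ab.push_back(b[j - 1]); --i; --j;
    } else if (j > 0 && (mv == 1 || i == 0)) {
      aa.push_back('-'); ab.push_back(b[j - 1]); --j;
    } else {
      aa.push_back(a[i - 1]); ab.push_back('-'); --i;
    }
  }
  std::reverse(aa.begin(), aa.end());
  std::reverse(ab.begin(), ab.end());
  return List::create(_["score"] = score,
                      _["aligned_a"] = aa,
                      _["aligned_b"] = ab);
}

// Semiglobal alignment: query fully consumed, free text (target) ends.
// Unit-cost substitutions/indels; per-position match cost 0 under `mode`:
//   0 exact character equality
//   1 primer-vs-read: text base must be a concrete A/C/G/T contained in the
//     query character's IUPAC set (an N in the read matches nothing)
//   2 IUPAC set intersection of both characters
// Returns the best occurrence: minimal distance, then smallest end position.
// start/end are 1-based text positions of the matched region (start > end
// means an empty region: the whole query aligned to gaps).
// [[Rcpp::export]]
List cpp_semiglobal(std::string q, std::string t, int mode) {
  iupac_init();
  const int n = q.size(), m = t.size();
  std::vector<int> prev(m + 1), cur(m + 1);
  std::vector<unsigned char> tb((size_t)(n + 1) * (m + 1));
  for (int j = 0; j <= m; ++j) { prev[j] = 0; tb[j] = 3; /* free start */ }
  for (int i = 1; i <= n; ++i) {
    cur[0] = i;
    tb[(size_t)i * (m + 1)] = 2;
    for (int j = 1; j <= m; ++j) {
      int cost;
      char qc = q[i - 1], tc = t[j - 1];
      if (mode == 0) {
        cost = (qc == tc) ? 0 : 1;
      } else if (mode == 1) {
        int bt = bits_of(tc);
        bool concrete = (bt == 1 || bt == 2 || bt == 4 || bt == 8);
        cost = (concrete && (bits_of(qc) & bt)) ? 0 : 1;
      } else {
        cost = (bits_of(qc) & bits_of(tc)) ? 0 : 1;
      }
      int d = prev[j - 1] + cost;
      int u = prev[j] + 1;      // consume query (gap in text)
      int l = cur[j - 1] + 1;   // consume text (gap in query)
      int best = d; unsigned char mv = 0;
      if (u < best) { best = u; mv = 2; }
      if (l < best) { best = l; mv = 1; }
      cur[j] = best;
      tb[(size_t)i * (m + 1) + j] = mv;
    }
    std::swap(prev, cur);
  }
  int bestj = 0, bestd = prev[0];
  for (int j = 1; j <= m; ++j) {
    if (prev[j] < bestd) { bestd = prev[j]; bestj = j; }
  }
  // traceback from (n, bestj) to row 0
  std::string aq, at;
  int i = n, j = bestj;
  while (i > 0) {
    unsigned char mv = tb[(size_t)i * (m + 1) + j];
    if (mv == 0) {
      aq.push_back(q[i - 1]); at.push_back(t[j - 1]); --i; --j;
    } else if (mv == 2) {
      aq.push_back(q[i - 1]); at.push_back('-'); --i;
    } else {
      aq.push_back('-'); at.push_back(t[j - 1]); --j;
    }
  }
  std::reverse(aq.begin(), aq.end());
  std::reverse(at.begin(), at.end());
  return List::create(_["dist"] = bestd,
                      _["start"] = j + 1,
                      _["end"] = bestj,
                      _["aligned_query"] = aq,
                      _["aligned_target"] = at);
}
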