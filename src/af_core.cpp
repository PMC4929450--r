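// Low-level string kernels for the alignment-free distances: k-mer and
// spaced-word counting, co-phylog context joins, suffix-automaton based
// matching statistics (acs/kmacs/kr) and LZ76 phrase counts (gram).
#include <Rcpp.h>
#include <array>
#include <cstdint>
#include <string>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (char& c : r) {
    switch (c) {
      case 'A': case 'a': c = 'T'; break;
      case 'C': case 'c': c = 'G'; break;
      case 'G': case 'g': c = 'C'; break;
      case 'T': case 't': c = 'A'; break;
      default: c = 'N'; break;
    }
  }
  return r;
}

// [[Rcpp::export]]
std::string cpp_revcomp(std::string s) { return revcomp(s); }

// ---------------------------------------------------------------------------
// k-mer counting (2-bit codes; windows containing non-ACGT skipped)

static void collect_kmer_codes(const std::string& s, int k,
                               std::vector<uint64_t>& out) {
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t code = 0;
  int run = 0;  // length of current valid run
  for (size_t i = 0; i < s.size(); ++i) {
    int c = base_code(s[i]);
    if (c < 0) { run = 0; code = 0; continue; }
    code = ((code << 2) | (uint64_t)c) & mask;
    if (++run >= k) out.push_back(code);
  }
}

static List codes_to_counts(std::vector<uint64_t>& codes) {
  std::sort(codes.begin(), codes.end());
  std::vector<double> uc;
  std::vector<double> cnt;
  size_t i = 0;
  while (i < codes.size()) {
    size_t j = i;
    while (j < codes.size() && codes[j] == codes[i]) ++j;
    uc.push_back((double)codes[i]);
    cnt.push_back((double)(j - i));
    i = j;
  }
  return List::create(_["codes"] = wrap(uc), _["counts"] = wrap(cnt));
}

// [[Rcpp::export]]
List cpp_kmer_counts(std::string seq, int k, bool both_strands) {
  if (k < 1 || k > 26) stop("k must be in [1, 26]");
  std::vector<uint64_t> codes;
  collect_kmer_codes(seq, k, codes);
  if (both_strands) {
    std::string rc = revcomp(seq);
    collect_kmer_codes(rc, k, codes);
  }
  return codes_to_counts(codes);
}

// Spaced words: pattern is a string of '1' (match) and '0' (don't care);
// the word is read off the match positions only.
static void collect_spaced_codes(const std::string& s,
                                 const std::vector<int>& offs, int plen,
                                 std::vector<uint64_t>& out) {
  int n = (int)s.size();
  for (int i = 0; i + plen <= n; ++i) {
    uint64_t code = 0;
    bool ok = true;
    for (int o : offs) {
      int c = base_code(s[i + o]);
      if (c < 0) { ok = false; break; }
      code = (code << 2) | (uint64_t)c;
    }
    if (ok) out.push_back(code);
  }
}

// [[Rcpp::export]]
List cpp_spaced_counts(std::string seq, std::string pattern,
                       bool both_strands) {
  std::vector<int> offs;
  for (size_t i = 0; i < pattern.size(); ++i)
    if (pattern[i] == '1') offs.push_back((int)i);
  if (offs.empty() || offs.size() > 26) stop("pattern weight must be in [1, 26]");
  std::vector<uint64_t> codes;
  collect_spaced_codes(seq, offs, (int)pattern.size(), codes);
  if (both_strands) {
    std::string rc = revcomp(seq);
    collect_spaced_codes(rc, offs, (int)pattern.size(), codes);
  }
  return codes_to_counts(codes);
}

// ---------------------------------------------------------------------------
// co-phylog: context = K nt either side of a single middle nt (the object).
// Contexts mapping to more than one object within a genome are discarded.

static void cophylog_map(const std::string& s, int K,
                         std::unordered_map<uint64_t, int>& map) {
  int n = (int)s.size(), w = 2 * K + 1;
  for (int i = 0; i + w <= n; ++i) {
    uint64_t key = 0;
    bool ok = true;
    int obj = -1;
    for (int j = 0; j < w; ++j) {
      int c = base_code(s[i + j]);
      if (c < 0) { ok = false; break; }
      if (j == K) obj = c;
      else key = (key << 2) | (uint64_t)c;
    }
    if (!ok) continue;
    auto it = map.find(key);
    if (it == map.end()) map.emplace(key, obj);
    else if (it->second != obj) it->second = -1;  // conflict: discard later
  }
}

// [[Rcpp::export]]
NumericVector cpp_cophylog_counts(std::string x, std::string y, int K,
                                  bool both_strands) {
  if (K < 1 || K > 15) stop("K must be in [1, 15]");
  std::unordered_map<uint64_t, int> mx, my;
  cophylog_map(x, K, mx);
  cophylog_map(y, K, my);
  if (both_strands) {
    cophylog_map(revcomp(x), K, mx);
    cophylog_map(revcomp(y), K, my);
  }
  double shared = 0, diff = 0;
  const auto& small = (mx.size() <= my.size()) ? mx : my;
  const auto& big = (mx.size() <= my.size()) ? my : mx;
  for (const auto& kv : small) {
    if (kv.second < 0) continue;
    auto it = big.find(kv.first);
    if (it == big.end() || it->second < 0) continue;
    shared += 1;
    if (it->second != kv.second) diff += 1;
  }
  return NumericVector::create(shared, diff);
}

// Full co-phylog distance matrix: context maps are built once per genome
// and joined pairwise. Returns an n x n matrix with NA where a pair shares
// no context.
// [[Rcpp::export]]
NumericMatrix cpp_cophylog_matrix(std::vector<std::string> seqs, int K,
                                  bool both_strands) {
  if (K < 1 || K > 15) stop("K must be in [1, 15]");
  int n = (int)seqs.size();
  std::vector<std::unordered_map<uint64_t, int>> maps(n);
  for (int i = 0; i < n; ++i) {
    cophylog_map(seqs[i], K, maps[i]);
    if (both_strands) cophylog_map(revcomp(seqs[i]), K, maps[i]);
  }
  NumericMatrix out(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const auto& small = (maps[i].size() <= maps[j].size()) ? maps[i]
                                                             : maps[j];
      const auto& big = (maps[i].size() <= maps[j].size()) ? maps[j]
                                                           : maps[i];
      double shared = 0, diff = 0;
      for (const auto& kv : small) {
        if (kv.second < 0) continue;
        auto it = big.find(kv.first);
        if (it == big.end() || it->second < 0) continue;
        shared += 1;
        if (it->second != kv.second) diff += 1;
      }
      out(i, j) = out(j, i) =
          (shared == 0) ? NA_REAL : diff / shared;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Suffix automaton with first-occurrence end positions.

struct SuffixAutomaton {
  std::vector<int> len, link, fpos;
  std::vector<std::array<int, 5>> nxt;
  int last;

  explicit SuffixAutomaton(size_t n) {
    len.reserve(2 * n + 4);
    link.reserve(2 * n + 4);
    fpos.reserve(2 * n + 4);
    nxt.reserve(2 * n + 4);
    add_state(0);
    link[0] = -1;
    last = 0;
  }
  int add_state(int l) {
    len.push_back(l);
    link.push_back(-1);
    fpos.push_back(-1);
    nxt.push_back({{-1, -1, -1, -1, -1}});
    return (int)len.size() - 1;
  }
  void extend(int c) {
    int cur = add_state(len[last] + 1);
    fpos[cur] = len[cur] - 1;
    int p = last;
    while (p != -1 && nxt[p][c] == -1) { nxt[p][c] = cur; p = link[p]; }
    if (p == -1) {
      link[cur] = 0;
    } else {
      int q = nxt[p][c];
      if (len[p] + 1 == len[q]) {
        link[cur] = q;
      } else {
        int clone = add_state(len[p] + 1);
        nxt[clone] = nxt[q];
        link[clone] = link[q];
        fpos[clone] = fpos[q];
        while (p != -1 && nxt[p][c] == q) { nxt[p][c] = clone; p = link[p]; }
        link[q] = clone;
        link[cur] = clone;
      }
    }
    last = cur;
  }
  void build(const std::string& s) {
    for (char ch : s) {
      int c = base_code(ch);
      extend(c < 0 ? 4 : c);
    }
  }
};

// Per-start matching statistics: ml[i] = length of the longest prefix of
// x[i..] that occurs as a substring of y.  Computed as per-end matching
// statistics on the reversed strings.  Non-ACGT characters never match.
// When `occ` is non-null it receives, per start, the 0-based position in y
// where the rightmost occurrence of that longest match begins (-1 if none).
static std::vector<int> per_start_ms(const std::string& x,
                                     const std::string& y,
                                     std::vector<int>* occ = nullptr) {
  std::string ry(y.rbegin(), y.rend());
  SuffixAutomaton sa(ry.size());
  sa.build(ry);
  int n = (int)x.size(), m = (int)y.size();
  std::vector<int> ms(n, 0);
  if (occ) occ->assign(n, -1);
  int v = 0, l = 0;
  // stream reversed x
  for (int j = 0; j < n; ++j) {
    int c = base_code(x[n - 1 - j]);
    if (c < 0) { v = 0; l = 0; ms[n - 1 - j] = 0; continue; }
    while (v != 0 && sa.nxt[v][c] == -1) { v = sa.link[v]; l = sa.len[v]; }
    if (sa.nxt[v][c] != -1) { v = sa.nxt[v][c]; ++l; } else { l = 0; }
    ms[n - 1 - j] = l;  // end j in reversed x == start n-1-j in x
    if (occ && l > 0) {
      // first occurrence end in ry == rightmost occurrence in y; the match
      // x[i..i+l-1] reads off y starting at m-1-fpos
      (*occ)[n - 1 - j] = m - 1 - sa.fpos[v];
    }
  }
  return ms;
}

// [[Rcpp::export]]
IntegerVector cpp_match_lengths(std::string x, std::string y,
                                bool both_strands) {
  std::vector<int> ms = per_start_ms(x, y);
  if (both_strands) {
    std::vector<int> ms2 = per_start_ms(x, revcomp(y));
    for (size_t i = 0; i < ms.size(); ++i)
      if (ms2[i] > ms[i]) ms[i] = ms2[i];
  }
  return wrap(ms);
}

// kmacs-style greedy lengths against one target strand: longest exact match,
// then extension across up to mm mismatch positions starting from the
// rightmost occurrence in y of that longest match.
static std::vector<int> kmacs_one_strand(const std::string& x,
                                         const std::string& y, int mm) {
  std::vector<int> occ;
  std::vector<int> ms = per_start_ms(x, y, &occ);
  if (mm <= 0) return ms;
  int n = (int)x.size(), m = (int)y.size();
  std::vector<int> out(n);
  for (int i = 0; i < n; ++i) {
    int l = ms[i];
    out[i] = l;
    if (l == 0) continue;
    int s0 = occ[i];
    int total = l, used = 0, xi = i + l, yi = s0 + l;
    while (used < mm && xi < n && yi < m) {
      if (base_code(x[xi]) < 0 || base_code(y[yi]) < 0) break;
      ++used; ++total; ++xi; ++yi;  // consume the guaranteed mismatch
      while (xi < n && yi < m && base_code(x[xi]) >= 0 &&
             x[xi] == y[yi]) {
        ++total; ++xi; ++yi;
      }
    }
    out[i] = total;
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_kmacs_lengths(std::string x, std::string y, int mm,
                                bool both_strands) {
  std::vector<int> a = kmacs_one_strand(x, y, mm);
  if (both_strands) {
    std::vector<int> b = kmacs_one_strand(x, revcomp(y), mm);
    for (size_t i = 0; i < a.size(); ++i)
      if (b[i] > a[i]) a[i] = b[i];
  }
  return wrap(a);
}

// Shortest unique (absent-from-y) prefix lengths: shulen[i] = ml[i] + 1,
// capped at the remaining suffix length when the whole suffix matches.
// [[Rcpp::export]]
IntegerVector cpp_shulens(std::string x, std::string y, bool both_strands) {
  IntegerVector ml = cpp_match_lengths(x, y, both_strands);
  int n = ml.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    int cap = n - i;
    out[i] = (ml[i] >= cap) ? cap : ml[i] + 1;
  }
  return out;
}

// ---------------------------------------------------------------------------
// LZ76 phrase count (exhaustive-history parsing) via suffix automaton with
// first-occurrence positions: each phrase is the longest prefix having an
// occurrence starting strictly earlier, plus one symbol.

// [[Rcpp::export]]
int cpp_lz_phrases(std::string s) {
  int n = (int)s.size();
  if (n == 0) return 0;
  SuffixAutomaton sa(s.size());
  sa.build(s);
  int count = 0, i = 0;
  while (i < n) {
    int v = 0, l = 0;
    while (i + l < n) {
      int c = base_code(s[i + l]);
      if (c < 0) c = 4;
      int w = sa.nxt[v][c];
      if (w == -1) break;
      // first occurrence of s[i..i+l] starts at fpos - l; require < i
      if (sa.fpos[w] - l >= i) break;
      v = w;
      ++l;
    }
    int take = std::min(l + 1, n - i);
    ++count;
    i += take;
  }
  return count;
}
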