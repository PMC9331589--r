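#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Minimum qualifying repeat count per core length.
// Must stay in sync with tr_qualifies() on the R side.
static inline int min_repeats(int L) {
  if (L == 1) return 6;
  if (L <= 9) return 3;
  return 2;
}

// core is primitive iff it is not a whole-number repetition of a shorter unit
static bool is_primitive(const char *s, int L) {
  for (int d = 1; d <= L / 2; ++d) {
    if (L % d != 0) continue;
    bool periodic = true;
    for (int i = d; i < L; ++i) {
      if (s[i] != s[i - d]) { periodic = false; break; }
    }
    if (periodic) return false;
  }
  return true;
}

struct Hits {
  std::vector<int> start, core_len, n_rep;
};

// Maximal-run scan via per-offset match runs: for each core length L,
// run[i] counts consecutive positions j >= i with s[j] == s[j+L] (N never
// matches), so a run starting at i holds run[i]/L + 1 full core copies.
// A start is left-maximal unless the previous L positions also match
// (run[i-L] >= L).  O(n * max_core).
static void scan_seq(const char *s, int n, int max_core, Hits &out) {
  std::vector<int> run((size_t) n + 1, 0);
  const int Lmax = std::min(max_core, n / 2);
  for (int L = 1; L <= Lmax; ++L) {
    const int minr = min_repeats(L);
    run[n] = 0;
    for (int i = n - 1; i >= 0; --i) {
      bool m = (i + L < n) && s[i] == s[i + L] && s[i] != 'N';
      run[i] = m ? run[i + 1] + 1 : 0;
    }
    for (int i = 0; i + 2 * L <= n; ++i) {
      int r = run[i] / L + 1;
      if (r < minr) continue;
      if (i >= L && run[i - L] >= L) continue;  // extendable left
      if (!is_primitive(s + i, L)) continue;
      out.start.push_back(i);
      out.core_len.push_back(L);
      out.n_rep.push_back(r);
    }
  }
}

static void check_alphabet(const char *s, int n) {
  for (int i = 0; i < n; ++i) {
    char c = s[i];
    if (c == 'A' || c == 'C' || c == 'G' || c == 'T' || c == 'N') continue;
    stop("invalid sequence character '%s' at position %d (expected A/C/G/T/N)",
         std::string(1, c).c_str(), i + 1);
  }
}

// [[Rcpp::export(name = ".tr_scan")]]
List tr_scan(std::string seq, int max_core) {
  const int n = (int) seq.size();
  const char *s = seq.c_str();
  check_alphabet(s, n);
  Hits h;
  scan_seq(s, n, max_core, h);
  return List::create(_["start"] = wrap(h.start),
                      _["core_length"] = wrap(h.core_len),
                      _["n_repeats"] = wrap(h.n_rep));
}

// batch scan: one call for many sequences, hits keyed by sequence index
// [[Rcpp::export(name = ".tr_scan_batch")]]
List tr_scan_batch(CharacterVector seqs, int max_core) {
  std::vector<int> idx, start, core_len, n_rep;
  for (int i = 0; i < seqs.size(); ++i) {
    std::string seq = as<std::string>(seqs[i]);
    const char *s = seq.c_str();
    const int n = (int) seq.size();
    check_alphabet(s, n);
    Hits h;
    scan_seq(s, n, max_core, h);
    for (size_t j = 0; j < h.start.size(); ++j) {
      idx.push_back(i + 1);
      start.push_back(h.start[j]);
      core_len.push_back(h.core_len[j]);
      n_rep.push_back(h.n_rep[j]);
    }
  }
  return List::create(_["seq_index"] = wrap(idx), _["start"] = wrap(start),
                      _["core_length"] = wrap(core_len),
                      _["n_repeats"] = wrap(n_rep));
}

// hits sorted by (start, core_len) equal the planted blocks?
static bool hits_match(const Hits &h, std::vector<int> starts,
                       std::vector<int> lens, std::vector<int> reps) {
  size_t k = starts.size();
  if (h.start.size() != k) return false;
  std::vector<size_t> oh(k), op(k);
  for (size_t i = 0; i < k; ++i) oh[i] = op[i] = i;
  auto byposH = [&](size_t a, size_t b) {
    return h.start[a] != h.start[b] ? h.start[a] < h.start[b]
                                    : h.core_len[a] < h.core_len[b];
  };
  auto byposP = [&](size_t a, size_t b) {
    return starts[a] != starts[b] ? starts[a] < starts[b]
                                  : lens[a] < lens[b];
  };
  std::sort(oh.begin(), oh.end(), byposH);
  std::sort(op.begin(), op.end(), byposP);
  for (size_t i = 0; i < k; ++i) {
    if (h.start[oh[i]] != starts[op[i]] || h.core_len[oh[i]] != lens[op[i]] ||
        h.n_rep[oh[i]] != reps[op[i]])
      return false;
  }
  return true;
}

static const char DNA[4] = {'A', 'C', 'G', 'T'};

// draw in [0, m) from R's RNG stream (deterministic under set.seed)
static inline int r_int(int m) {
  int v;
  do { v = (int) (unif_rand() * m); } while (v >= m);
  return v;
}

// Build one upstream window of length W containing exactly the planted
// blocks (core i repeated count i times) at random non-overlapping
// positions (>= 1 bp apart) on an i.i.d. ACGT background.  Draws whose
// detected hit set differs from the plant are rejected.  Returns NULL
// when the blocks cannot fit, and errors after max_tries rejections.
// [[Rcpp::export(name = ".build_upstream_cpp")]]
SEXP build_upstream_cpp(CharacterVector cores, IntegerVector counts, int W,
                        int max_core, int max_tries) {
  const int k = cores.size();
  std::vector<std::string> block(k);
  std::vector<int> lens(k), Ls(k);
  int total = 0;
  for (int i = 0; i < k; ++i) {
    std::string core = as<std::string>(cores[i]);
    Ls[i] = (int) core.size();
    std::string b;
    for (int r = 0; r < counts[i]; ++r) b += core;
    block[i] = b;
    lens[i] = (int) b.size();
    total += lens[i];
  }
  if (k > 0 && total + (k - 1) > W) return R_NilValue;  // infeasible

  GetRNGstate();
  std::string seq((size_t) W, 'A');
  std::vector<int> pos(k), ord(k);
  std::vector<int> starts(k), plens(Ls), reps(counts.begin(), counts.end());
  for (int t = 1; t <= max_tries; ++t) {
    for (int i = 0; i < W; ++i) seq[i] = DNA[r_int(4)];
    if (k > 0) {
      for (int i = 0; i < k; ++i) ord[i] = i;
      for (int i = k - 1; i > 0; --i) std::swap(ord[i], ord[r_int(i + 1)]);
      int slack = W - total - (k - 1);
      std::vector<int> alloc(k + 1, 0);
      for (int u = 0; u < slack; ++u) alloc[r_int(k + 1)]++;
      int cur = 0;
      for (int j = 0; j < k; ++j) {
        cur += alloc[j] + (j > 0 ? 1 : 0);
        int b = ord[j];
        pos[b] = cur;
        seq.replace((size_t) cur, (size_t) lens[b], block[b]);
        cur += lens[b];
      }
      starts = pos;
    }
    Hits h;
    scan_seq(seq.c_str(), W, max_core, h);
    if (hits_match(h, starts, plens, reps)) {
      PutRNGstate();
      return List::create(_["seq"] = seq, _["starts"] = wrap(starts),
                          _["tries"] = t);
    }
  }
  PutRNGstate();
  stop("could not realise a clean upstream sequence after %d draws "
       "(window too crowded?)", max_tries);
}
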