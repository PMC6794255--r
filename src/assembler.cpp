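// Single-k De Bruijn assembler over canonical k-mers: count filter, tip
// clipping, simple bubble popping, maximal unbranched path extraction.
// Stands in for the isoform-aware assembler used on real transcriptomes;
// the target here is a single ~16 kb near-uniformly transcribed molecule.
#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <algorithm>

using namespace Rcpp;

static inline int b2i(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  }
  return -1;
}
static const char BASES[4] = {'A', 'C', 'G', 'T'};

static inline uint64_t rc_kmer(uint64_t x, int k) {
  uint64_t r = 0;
  for (int i = 0; i < k; ++i) {
    r = (r << 2) | (3ULL - (x & 3ULL));
    x >>= 2;
  }
  return r;
}
static inline uint64_t canon(uint64_t x, int k) {
  uint64_t r = rc_kmer(x, k);
  return x < r ? x : r;
}

struct Graph {
  int k;
  uint64_t mask;
  std::unordered_map<uint64_t, uint32_t> cnt;  // canonical k-mer -> count
  bool has(uint64_t oriented) const { return cnt.count(canon(oriented, k)) > 0; }
  uint32_t count(uint64_t oriented) const {
    auto it = cnt.find(canon(oriented, k));
    return it == cnt.end() ? 0 : it->second;
  }
  int succ(uint64_t x, uint64_t out[4]) const {
    int n = 0;
    for (uint64_t b = 0; b < 4; ++b) {
      uint64_t nxt = ((x << 2) | b) & mask;
      if (has(nxt)) out[n++] = nxt;
    }
    return n;
  }
  int pred(uint64_t x, uint64_t out[4]) const {
    int n = 0;
    for (uint64_t b = 0; b < 4; ++b) {
      uint64_t prv = (x >> 2) | (b << (2 * (k - 1)));
      if (has(prv)) out[n++] = prv;
    }
    return n;
  }
};

static std::string kmer_str(uint64_t x, int k) {
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) { s[i] = BASES[x & 3]; x >>= 2; }
  return s;
}

// Walk a maximal unbranched path forward from an oriented k-mer.
// Stops when the current node has != 1 successor or the successor has
// != 1 predecessor, or when the walk returns to the start (cycle).
static std::vector<uint64_t> walk(const Graph& g, uint64_t start) {
  std::vector<uint64_t> path{start};
  uint64_t out[4], in[4];
  uint64_t cur = start;
  while (true) {
    if (g.succ(cur, out) != 1) break;
    uint64_t nxt = out[0];
    if (g.pred(nxt, in) != 1) break;
    if (nxt == start) { path.push_back(nxt); break; }  // closed a cycle
    // self-loop / palindromic guard
    if (nxt == cur) break;
    path.push_back(nxt);
    cur = nxt;
  }
  return path;
}

static std::string path_seq(const std::vector<uint64_t>& path, int k) {
  std::string s = kmer_str(path[0], k);
  for (size_t i = 1; i < path.size(); ++i)
    s.push_back(BASES[path[i] & 3]);
  return s;
}

struct Unitig {
  std::vector<uint64_t> nodes;  // oriented
  std::string seq;
  double mean_cov;
  bool circular;
};

// Collect unitig start nodes deterministically and extract unitigs.
static std::vector<Unitig> unitigs(const Graph& g) {
  // sorted canonical k-mers for deterministic iteration
  std::vector<uint64_t> keys;
  keys.reserve(g.cnt.size());
  for (auto& kv : g.cnt) keys.push_back(kv.first);
  std::sort(keys.begin(), keys.end());

  std::unordered_map<uint64_t, char> used;  // canonical -> visited
  std::vector<Unitig> out;

  auto is_start = [&](uint64_t x) {
    // oriented x starts a unitig if its predecessor side is not a simple
    // 1-in/1-out continuation
    uint64_t in[4];
    int np = g.pred(x, in);
    if (np != 1) return true;
    uint64_t sucs[4];
    if (g.succ(in[0], sucs) != 1) return true;
    return false;
  };

  for (uint64_t key : keys) {
    if (used.count(key)) continue;
    for (int ori = 0; ori < 2; ++ori) {
      uint64_t x = ori == 0 ? key : rc_kmer(key, g.k);
      if (ori == 1 && x == key) continue;
      if (!is_start(x)) continue;
      std::vector<uint64_t> path = walk(g, x);
      bool closed = path.size() > 1 && path.back() == path.front();
      if (closed) path.pop_back();
      bool fresh = true;
      for (uint64_t n : path) if (used.count(canon(n, g.k))) { fresh = false; break; }
      if (!fresh) continue;
      for (uint64_t n : path) used[canon(n, g.k)] = 1;
      Unitig u;
      u.nodes = path;
      u.circular = false;
      u.seq = path_seq(path, g.k);
      double s = 0;
      for (uint64_t n : path) s += g.count(n);
      u.mean_cov = s / path.size();
      out.push_back(std::move(u));
      break;
    }
  }
  // remaining nodes belong to pure cycles (no branch anywhere): emit each
  // cycle once, starting at its smallest canonical k-mer, with extra
  // terminal redundancy so circularity is detectable downstream.
  for (uint64_t key : keys) {
    if (used.count(key)) continue;
    std::vector<uint64_t> path = walk(g, key);
    bool closed = path.size() > 1 && path.back() == path.front();
    if (closed) path.pop_back();
    bool fresh = true;
    for (uint64_t n : path) if (used.count(canon(n, g.k))) { fresh = false; break; }
    if (!fresh) continue;
    for (uint64_t n : path) used[canon(n, g.k)] = 1;
    Unitig u;
    u.nodes = path;
    u.circular = closed;
    u.seq = path_seq(path, g.k);
    if (closed) {
      // append 61 wrapped nodes => >= 60 bp terminal self-overlap
      size_t extra = std::min(path.size(), (size_t)61);
      for (size_t i = 0; i < extra; ++i)
        u.seq.push_back(BASES[path[i % path.size()] & 3]);
    }
    double s = 0;
    for (uint64_t n : path) s += g.count(n);
    u.mean_cov = s / path.size();
    out.push_back(std::move(u));
  }
  return out;
}

// Remove short dead-end unitigs (tips).  Returns number removed.
static int clip_tips(Graph& g, int max_tip_bases) {
  std::vector<Unitig> us = unitigs(g);
  uint64_t tmp[4];
  int removed = 0;
  for (auto& u : us) {
    if (u.circular) continue;
    if ((int)u.seq.size() >= max_tip_bases) continue;
    bool dead_front = g.pred(u.nodes.front(), tmp) == 0;
    bool dead_back = g.succ(u.nodes.back(), tmp) == 0;
    if (!(dead_front || dead_back)) continue;
    if (dead_front && dead_back) continue;  // isolated islet, handled by min_len
    for (uint64_t n : u.nodes) g.cnt.erase(canon(n, g.k));
    ++removed;
  }
  return removed;
}

static double seq_identity(const std::string& a, const std::string& b) {
  size_t n = std::min(a.size(), b.size());
  if (n == 0) return 0.0;
  size_t m = 0;
  for (size_t i = 0; i < n; ++i) if (a[i] == b[i]) ++m;
  return (double)m / (double)std::max(a.size(), b.size());
}

// Pop simple two-branch bubbles: equal-anchor branch pairs whose sequences
// are near-identical keep the higher-coverage branch.
static int pop_bubbles(Graph& g, double bubble_identity, int max_branch) {
  std::vector<uint64_t> keys;
  for (auto& kv : g.cnt) keys.push_back(kv.first);
  std::sort(keys.begin(), keys.end());
  uint64_t out[4];
  int popped = 0;
  for (uint64_t key : keys) {
    if (!g.cnt.count(key)) continue;
    for (int ori = 0; ori < 2; ++ori) {
      uint64_t x = ori == 0 ? key : rc_kmer(key, g.k);
      int ns = g.succ(x, out);
      if (ns != 2) continue;
      // walk each branch
      std::vector<uint64_t> p1 = walk(g, out[0]);
      std::vector<uint64_t> p2 = walk(g, out[1]);
      if ((int)p1.size() > max_branch || (int)p2.size() > max_branch) continue;
      uint64_t s1[4], s2[4];
      if (g.succ(p1.back(), s1) != 1 || g.succ(p2.back(), s2) != 1) continue;
      if (s1[0] != s2[0]) continue;  // must reconverge on the same node
      std::string q1 = path_seq(p1, g.k), q2 = path_seq(p2, g.k);
      if (seq_identity(q1, q2) < bubble_identity) continue;
      double c1 = 0, c2 = 0;
      for (uint64_t n : p1) c1 += g.count(n);
      for (uint64_t n : p2) c2 += g.count(n);
      c1 /= p1.size(); c2 /= p2.size();
      const std::vector<uint64_t>& loser = (c1 >= c2) ? p2 : p1;
      for (uint64_t n : loser) g.cnt.erase(canon(n, g.k));
      ++popped;
    }
  }
  return popped;
}

// [[Rcpp::export]]
List cpp_assemble(CharacterVector reads, int k, int min_kmer_count,
                  int min_contig_len, double bubble_identity) {
  if (k < 15 || k % 2 == 0) stop("dbg_k must be odd and >= 15");
  if (k > 31) stop("dbg_k must be <= 31");
  Graph g;
  g.k = k;
  g.mask = (1ULL << (2 * k)) - 1;

  bool any_long_enough = false;
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    const char* s = CHAR(STRING_ELT(reads, r));
    int len = (int)LENGTH(STRING_ELT(reads, r));
    if (len >= k) any_long_enough = true;
    uint64_t val = 0;
    int run = 0;
    for (int i = 0; i < len; ++i) {
      int v = b2i(s[i]);
      if (v < 0) { run = 0; val = 0; continue; }
      val = ((val << 2) | (uint64_t)v) & g.mask;
      if (++run >= k) g.cnt[canon(val, k)]++;
    }
  }
  if (!any_long_enough) {
    Rf_warning("all reads shorter than dbg_k = %d; empty assembly", k);
    return List::create(_["seq"] = CharacterVector(0),
                        _["mean_cov"] = NumericVector(0),
                        _["circular"] = LogicalVector(0));
  }
  if (min_kmer_count > 1) {
    for (auto it = g.cnt.begin(); it != g.cnt.end();) {
      if (it->second < (uint32_t)min_kmer_count) it = g.cnt.erase(it);
      else ++it;
    }
  }
  // graph cleaning: tips then bubbles, a few rounds each
  for (int round = 0; round < 5; ++round)
    if (clip_tips(g, 2 * k) == 0) break;
  for (int round = 0; round < 3; ++round)
    if (pop_bubbles(g, bubble_identity, 3 * k) == 0) break;
  for (int round = 0; round < 3; ++round)
    if (clip_tips(g, 2 * k) == 0) break;

  std::vector<Unitig> us = unitigs(g);
  // canonical orientation + deterministic order (length desc, then sequence)
  std::vector<std::pair<std::string, std::pair<double, bool>>> rows;
  for (auto& u : us) {
    if ((int)u.seq.size() < min_contig_len) continue;
    std::string rc(u.seq.rbegin(), u.seq.rend());
    for (auto& c : rc) c = BASES[3 - b2i(c)];
    std::string s = std::min(u.seq, rc);
    rows.push_back({s, {u.mean_cov, u.circular}});
  }
  std::sort(rows.begin(), rows.end(), [](const auto& a, const auto& b) {
    if (a.first.size() != b.first.size()) return a.first.size() > b.first.size();
    return a.first < b.first;
  });
  int n = (int)rows.size();
  CharacterVector seq(n);
  NumericVector cov(n);
  LogicalVector circ(n);
  for (int i = 0; i < n; ++i) {
    seq[i] = rows[i].first;
    cov[i] = rows[i].second.first;
    circ[i] = rows[i].second.second;
  }
  return List::create(_["seq"] = seq, _["mean_cov"] = cov, _["circular"] = circ);
}

// Assign each read to the contig sharing most of its k-mers (-1 = none).
// [[Rcpp::export]]
IntegerVector cpp_assign_reads(CharacterVector contigs, CharacterVector reads,
                               int k) {
  uint64_t mask = (1ULL << (2 * k)) - 1;
  std::unordered_map<uint64_t, int32_t> owner;  // canonical k-mer -> contig
  for (R_xlen_t c = 0; c < contigs.size(); ++c) {
    const char* s = CHAR(STRING_ELT(contigs, c));
    int len = (int)LENGTH(STRING_ELT(contigs, c));
    uint64_t val = 0; int run = 0;
    for (int i = 0; i < len; ++i) {
      int v = b2i(s[i]);
      if (v < 0) { run = 0; val = 0; continue; }
      val = ((val << 2) | (uint64_t)v) & mask;
      if (++run >= k) {
        uint64_t cn = canon(val, k);
        if (!owner.count(cn)) owner[cn] = (int32_t)c;  // first contig wins ties
      }
    }
  }
  IntegerVector out(reads.size());
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    const char* s = CHAR(STRING_ELT(reads, r));
    int len = (int)LENGTH(STRING_ELT(reads, r));
    std::unordered_map<int32_t, int> votes;
    uint64_t val = 0; int run = 0;
    for (int i = 0; i < len; ++i) {
      int v = b2i(s[i]);
      if (v < 0) { run = 0; val = 0; continue; }
      val = ((val << 2) | (uint64_t)v) & mask;
      if (++run >= k) {
        auto it = owner.find(canon(val, k));
        if (it != owner.end()) votes[it->second]++;
      }
    }
    int best = -1, bestv = 0;
    for (auto& kv : votes)
      if (kv.second > bestv || (kv.second == bestv && best >= 0 && kv.first < best)) {
        best = kv.first; bestv = kv.second;
      }
    out[r] = best < 0 ? NA_INTEGER : best + 1;
  }
  return out;
}
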