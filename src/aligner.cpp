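// Seeded local alignment: the in-package stand-in for the sensitive local
// mapper used during read baiting.  Exact k-mer seeds (plus the Hamming-1
// neighbourhood when the exact pass finds nothing) locate candidate
// diagonals; each diagonal is scored by a best-local-segment scan, with a
// banded Smith-Waterman fallback for near-threshold cases.  The simulated
// world is substitution-only, so the gapless scan is the common path.
#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <algorithm>
#include <cmath>

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

static std::string revcomp_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) {
    int v = b2i(c);
    c = (v < 0) ? 'N' : BASES[3 - v];
  }
  return r;
}

struct SeedIndex {
  int k;
  std::vector<std::string> ids;
  std::vector<std::string> seqs;
  std::vector<int> id_rank;  // rank of each reference when ids are sorted
  std::unordered_map<uint64_t, std::vector<std::pair<int32_t, int32_t>>> tab;
  // direct-address presence bitmap (4^k bits) for k <= 13: most seed
  // probes are misses, so an O(1) bit test beats a hash lookup
  std::vector<uint64_t> present;
  bool maybe(uint64_t v) const {
    if (present.empty()) return true;
    return (present[v >> 6] >> (v & 63)) & 1ULL;
  }
};

// [[Rcpp::export]]
SEXP cpp_index_build(CharacterVector ids, CharacterVector seqs, int k) {
  if (seqs.size() == 0) stop("reference set is empty");
  if (k < 2 || k > 31) stop("seed length k must be in [2, 31]");
  SeedIndex* idx = new SeedIndex();
  idx->k = k;
  uint64_t mask = (1ULL << (2 * k)) - 1;
  for (R_xlen_t r = 0; r < seqs.size(); ++r) {
    std::string s = as<std::string>(seqs[r]);
    for (auto& c : s) c = toupper(c);
    idx->ids.push_back(as<std::string>(ids[r]));
    idx->seqs.push_back(s);
    if ((int)s.size() < k) {
      Rf_warning("reference '%s' is shorter than k = %d; not indexed",
                 idx->ids.back().c_str(), k);
      continue;
    }
    uint64_t val = 0;
    int run = 0;
    for (size_t i = 0; i < s.size(); ++i) {
      int v = b2i(s[i]);
      if (v < 0) { run = 0; val = 0; continue; }
      val = ((val << 2) | (uint64_t)v) & mask;
      if (++run >= k)
        idx->tab[val].push_back({(int32_t)r, (int32_t)(i + 1 - k)});
    }
  }
  // lexicographic rank of reference ids, for deterministic tie-breaking
  std::vector<int> ord(idx->ids.size());
  for (size_t i = 0; i < ord.size(); ++i) ord[i] = (int)i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (idx->ids[a] != idx->ids[b]) return idx->ids[a] < idx->ids[b];
    return a < b;
  });
  idx->id_rank.resize(ord.size());
  for (size_t i = 0; i < ord.size(); ++i) idx->id_rank[ord[i]] = (int)i;
  if (k <= 13) {
    idx->present.assign(((1ULL << (2 * k)) + 63) / 64, 0ULL);
    for (auto& kv : idx->tab)
      idx->present[kv.first >> 6] |= 1ULL << (kv.first & 63);
  }
  XPtr<SeedIndex> p(idx, true);
  return p;
}

// [[Rcpp::export]]
List cpp_index_info(SEXP xp) {
  XPtr<SeedIndex> idx(xp);
  size_t nkmer = idx->tab.size(), npos = 0;
  for (auto& kv : idx->tab) npos += kv.second.size();
  return List::create(_["k"] = idx->k,
                      _["n_refs"] = (int)idx->ids.size(),
                      _["n_kmers"] = (double)nkmer,
                      _["n_positions"] = (double)npos,
                      _["ids"] = wrap(idx->ids));
}

// [[Rcpp::export]]
List cpp_index_query(SEXP xp, std::string kmer) {
  // positions of one exact k-mer on the indexed (forward) strand
  XPtr<SeedIndex> idx(xp);
  if ((int)kmer.size() != idx->k) stop("query length != index k");
  uint64_t val = 0;
  for (char c : kmer) {
    int v = b2i(c);
    if (v < 0) return List::create(_["ref"] = IntegerVector(0),
                                   _["pos"] = IntegerVector(0));
    val = (val << 2) | (uint64_t)v;
  }
  auto it = idx->tab.find(val);
  if (it == idx->tab.end())
    return List::create(_["ref"] = IntegerVector(0), _["pos"] = IntegerVector(0));
  int n = (int)it->second.size();
  IntegerVector ref(n), pos(n);
  for (int i = 0; i < n; ++i) {
    ref[i] = it->second[i].first + 1;
    pos[i] = it->second[i].second;
  }
  return List::create(_["ref"] = ref, _["pos"] = pos);
}

struct Hit {
  int ref;
  int strand;     // 0 = '+', 1 = '-'
  int qs, qe;     // on the original read, half-open
  int rs, re;     // on the reference, half-open
  double score;
  double identity;
};

struct AlnParams {
  double match, mismatch, gap_open, gap_extend;
  double min_a, min_b;
  int seed_mm;
  double min_score(int L) const { return min_a + min_b * std::log((double)L); }
};

// Best local segment along one gapless diagonal (Kadane on per-base scores).
// qseq is the strand-oriented query.  Returns true if a segment scored > 0.
static bool kadane_diag(const std::string& qseq, const std::string& rseq,
                        int diag, const AlnParams& p,
                        double& best, int& bqs, int& bqe, int& matches) {
  int L = (int)qseq.size(), R = (int)rseq.size();
  int i0 = std::max(0, -diag), i1 = std::min(L, R - diag);
  if (i1 - i0 <= 0) return false;
  double cur = 0, bestv = 0;
  int cur_start = i0, best_s = i0, best_e = i0;
  for (int i = i0; i < i1; ++i) {
    char a = qseq[i], b = rseq[i + diag];
    double sc = (a == b && a != 'N') ? p.match : p.mismatch;
    if (cur <= 0) { cur = sc; cur_start = i; }
    else cur += sc;
    if (cur > bestv) { bestv = cur; best_s = cur_start; best_e = i + 1; }
  }
  if (bestv <= 0) return false;
  best = bestv; bqs = best_s; bqe = best_e;
  matches = 0;
  for (int i = best_s; i < best_e; ++i)
    if (qseq[i] == rseq[i + diag] && qseq[i] != 'N') ++matches;
  return true;
}

// Full Smith-Waterman over a reference window (affine-ish: linear per-gap
// open+extend approximated with open on first gap base).  Window sizes are
// small (read-scale), so an O(L*W) DP with direction traceback is fine.
static bool sw_window(const std::string& q, const std::string& rseq,
                      int w0, int w1, const AlnParams& p,
                      double& score, int& qs, int& qe, int& rs, int& re,
                      int& matches) {
  int L = (int)q.size();
  w0 = std::max(0, w0); w1 = std::min((int)rseq.size(), w1);
  int W = w1 - w0;
  if (W <= 0) return false;
  std::vector<double> H((size_t)(L + 1) * (W + 1), 0.0);
  std::vector<uint8_t> D((size_t)(L + 1) * (W + 1), 0);  // 0 stop,1 diag,2 up,3 left
  double best = 0; int bi = 0, bj = 0;
  for (int i = 1; i <= L; ++i) {
    for (int j = 1; j <= W; ++j) {
      char a = q[i - 1], b = rseq[w0 + j - 1];
      double sc = (a == b && a != 'N') ? p.match : p.mismatch;
      double d = H[(size_t)(i - 1) * (W + 1) + (j - 1)] + sc;
      double u = H[(size_t)(i - 1) * (W + 1) + j] + p.gap_open + p.gap_extend;
      double l = H[(size_t)i * (W + 1) + (j - 1)] + p.gap_open + p.gap_extend;
      double h = std::max({0.0, d, u, l});
      uint8_t dir = 0;
      if (h > 0) { if (h == d) dir = 1; else if (h == u) dir = 2; else dir = 3; }
      H[(size_t)i * (W + 1) + j] = h;
      D[(size_t)i * (W + 1) + j] = dir;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  if (best <= 0) return false;
  int i = bi, j = bj; matches = 0;
  while (i > 0 && j > 0 && D[(size_t)i * (W + 1) + j] != 0) {
    uint8_t dir = D[(size_t)i * (W + 1) + j];
    if (dir == 1) {
      if (q[i - 1] == rseq[w0 + j - 1] && q[i - 1] != 'N') ++matches;
      --i; --j;
    } else if (dir == 2) --i;
    else --j;
  }
  score = best; qs = i; qe = bi; rs = w0 + j; re = w0 + bj;
  return true;
}

static void gather_cands(const SeedIndex& idx, const std::string& qseq,
                         bool neighbours,
                         std::vector<std::pair<int, int>>& cands) {
  int k = idx.k, L = (int)qseq.size();
  uint64_t mask = (1ULL << (2 * k)) - 1;
  uint64_t val = 0;
  int run = 0;
  for (int i = 0; i < L; ++i) {
    int v = b2i(qseq[i]);
    if (v < 0) { run = 0; val = 0; continue; }
    val = ((val << 2) | (uint64_t)v) & mask;
    if (++run < k) continue;
    int qpos = i + 1 - k;
    if (idx.maybe(val)) {
      auto it = idx.tab.find(val);
      if (it != idx.tab.end())
        for (auto& rp : it->second) cands.push_back({rp.first, rp.second - qpos});
    }
    if (neighbours) {
      for (int pos = 0; pos < k; ++pos)
        for (uint64_t m = 1; m <= 3; ++m) {
          uint64_t nb = val ^ (m << (2 * pos));
          if (!idx.maybe(nb)) continue;
          auto jt = idx.tab.find(nb);
          if (jt != idx.tab.end())
            for (auto& rp : jt->second)
              cands.push_back({rp.first, rp.second - qpos});
        }
    }
  }
  std::sort(cands.begin(), cands.end());
  cands.erase(std::unique(cands.begin(), cands.end()), cands.end());
}

static void eval_cands(const SeedIndex& idx, const std::string& qseq,
                       int strand, int origL,
                       const std::vector<std::pair<int, int>>& cands,
                       const AlnParams& p, std::vector<Hit>& hits) {
  double minsc = p.min_score(origL);
  int L = (int)qseq.size();
  for (auto& cd : cands) {
    const std::string& rseq = idx.seqs[cd.first];
    double sc; int qs, qe, m;
    bool ok = kadane_diag(qseq, rseq, cd.second, p, sc, qs, qe, m);
    if (!ok) continue;
    int rs = qs + cd.second, re = qe + cd.second;
    if (sc < minsc && sc >= minsc + 2.0 * (p.gap_open + p.gap_extend)) {
      // near miss: allow an indel-containing rescue in a small band
      double sc2; int qs2, qe2, rs2, re2, m2;
      int w0 = cd.second + qs - 12, w1 = cd.second + qe + 12;
      if (sw_window(qseq, rseq, w0, w1, p, sc2, qs2, qe2, rs2, re2, m2) &&
          sc2 > sc) {
        sc = sc2; qs = qs2; qe = qe2; rs = rs2; re = re2; m = m2;
      }
    }
    if (sc < minsc) continue;
    Hit h;
    h.ref = cd.first;
    h.strand = strand;
    // report intervals on the original read orientation
    if (strand == 0) { h.qs = qs; h.qe = qe; }
    else { h.qs = L - qe; h.qe = L - qs; }
    h.rs = rs; h.re = re;
    h.score = sc;
    h.identity = (qe > qs) ? (double)m / (double)(qe - qs) : 0.0;
    hits.push_back(h);
  }
}

static void sort_hits(const SeedIndex& idx, std::vector<Hit>& hits) {
  std::sort(hits.begin(), hits.end(), [&](const Hit& a, const Hit& b) {
    if (a.score != b.score) return a.score > b.score;
    if (idx.id_rank[a.ref] != idx.id_rank[b.ref])
      return idx.id_rank[a.ref] < idx.id_rank[b.ref];
    if (a.rs != b.rs) return a.rs < b.rs;
    return a.strand < b.strand;
  });
}

static std::vector<Hit> align_one(const SeedIndex& idx, const std::string& read,
                                  const AlnParams& p) {
  std::vector<Hit> hits;
  std::string fwd = read;
  for (auto& c : fwd) c = toupper(c);
  std::string rev = revcomp_str(fwd);
  int L = (int)fwd.size();
  for (int pass = 0; pass < 2; ++pass) {
    bool nb = (pass == 1);
    if (nb && (p.seed_mm < 1 || idx.k > 12)) break;
    for (int strand = 0; strand < 2; ++strand) {
      const std::string& q = (strand == 0) ? fwd : rev;
      std::vector<std::pair<int, int>> cands;
      gather_cands(idx, q, nb, cands);
      eval_cands(idx, q, strand, L, cands, p, hits);
    }
    if (!hits.empty()) break;  // neighbour pass only when exact pass is empty
  }
  // drop duplicate placements (same ref/strand/intervals) kept from both passes
  sort_hits(idx, hits);
  hits.erase(std::unique(hits.begin(), hits.end(), [](const Hit& a, const Hit& b) {
    return a.ref == b.ref && a.strand == b.strand && a.qs == b.qs &&
           a.qe == b.qe && a.rs == b.rs && a.re == b.re;
  }), hits.end());
  return hits;
}

static AlnParams make_params(List par) {
  AlnParams p;
  p.match = as<double>(par["match"]);
  p.mismatch = as<double>(par["mismatch"]);
  p.gap_open = as<double>(par["gap_open"]);
  p.gap_extend = as<double>(par["gap_extend"]);
  p.min_a = as<double>(par["min_score_a"]);
  p.min_b = as<double>(par["min_score_b"]);
  p.seed_mm = as<int>(par["seed_mismatches"]);
  return p;
}

static DataFrame hits_frame(const SeedIndex& idx, const std::vector<Hit>& hits,
                            const std::vector<int>* read_of = nullptr) {
  int n = (int)hits.size();
  IntegerVector ref(n), qs(n), qe(n), rs(n), re(n), rd(n);
  CharacterVector strand(n);
  NumericVector score(n), ident(n);
  for (int i = 0; i < n; ++i) {
    ref[i] = hits[i].ref + 1;
    strand[i] = hits[i].strand == 0 ? "+" : "-";
    qs[i] = hits[i].qs; qe[i] = hits[i].qe;
    rs[i] = hits[i].rs; re[i] = hits[i].re;
    score[i] = hits[i].score; ident[i] = hits[i].identity;
    rd[i] = read_of ? (*read_of)[i] : 1;
  }
  return DataFrame::create(_["read"] = rd, _["ref"] = ref, _["strand"] = strand,
                           _["qstart"] = qs, _["qend"] = qe,
                           _["rstart"] = rs, _["rend"] = re,
                           _["score"] = score, _["identity"] = ident,
                           _["stringsAsFactors"] = false);
}

// [[Rcpp::export]]
DataFrame cpp_align_local(SEXP xp, std::string read, List par) {
  XPtr<SeedIndex> idx(xp);
  AlnParams p = make_params(par);
  std::vector<Hit> hits = align_one(*idx, read, p);
  return hits_frame(*idx, hits);
}

// Batch recruitment: best hit per read (empty row skipped for unrecruited).
// [[Rcpp::export]]
DataFrame cpp_recruit_batch(SEXP xp, CharacterVector reads, List par) {
  XPtr<SeedIndex> idx(xp);
  AlnParams p = make_params(par);
  std::vector<Hit> best;
  std::vector<int> read_of;
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    std::vector<Hit> hits = align_one(*idx, as<std::string>(reads[i]), p);
    if (!hits.empty()) {
      best.push_back(hits[0]);
      read_of.push_back((int)i + 1);
    }
    if ((i & 0x3FF) == 0) Rcpp::checkUserInterrupt();
  }
  return hits_frame(*idx, best, &read_of);
}

// Sliding-window quality trim (Trimmomatic LEADING/TRAILING/SLIDINGWINDOW
// semantics).  Returns an n x 2 matrix of 0-based half-open keep intervals.
// [[Rcpp::export]]
IntegerMatrix cpp_quality_trim(CharacterVector quals, int leading, int trailing,
                               int window_len, double window_q) {
  int n = (int)quals.size();
  IntegerMatrix out(n, 2);
  for (int r = 0; r < n; ++r) {
    const char* q = CHAR(STRING_ELT(quals, r));
    int len = (int)LENGTH(STRING_ELT(quals, r));
    int s = 0, e = len;
    while (s < e && (q[s] - 33) < leading) ++s;
    while (e > s && (q[e - 1] - 33) < trailing) --e;
    if (window_len > 0 && e > s) {
      int L = e - s;
      int w = std::min(window_len, L);
      double sum = 0;
      for (int i = 0; i < w; ++i) sum += q[s + i] - 33;
      int cut = -1;
      if (sum / w < window_q) cut = 0;
      for (int i = 1; cut < 0 && i + w <= L; ++i) {
        sum += (q[s + i + w - 1] - 33) - (q[s + i - 1] - 33);
        if (sum / w < window_q) cut = i;
      }
      if (cut >= 0) e = s + cut;
    }
    out(r, 0) = s;
    out(r, 1) = e;
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector seqs) {
  CharacterVector out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i)
    out[i] = revcomp_str(as<std::string>(seqs[i]));
  return out;
}
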