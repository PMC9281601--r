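// Internal alignment backend: exact k-mer seeding, diagonal ungapped
// screening, and full affine-gap Smith-Waterman with traceback on surviving
// candidate pairs. Plus strand only; one HSP (the optimal local alignment)
// per query-subject pair.
#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <string>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

namespace {

inline int nt_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default: return -1;
  }
}

struct AlnStats {
  int score = 0, length = 0, matches = 0, mismatch = 0, gapopen = 0;
  int qstart = 0, qend = 0, sstart = 0, send = 0;
};

// Affine-gap local alignment; gap of length L costs gap_open + L*gap_extend.
// Tie-break: best end cell with smallest (query end, subject end); traceback
// prefers diagonal over vertical over horizontal. Deterministic.
AlnStats sw_align(const std::string& q, const std::string& s, int match,
                  int mismatch, int gap_open, int gap_extend) {
  const int m = static_cast<int>(q.size());
  const int n = static_cast<int>(s.size());
  AlnStats out;
  if (m == 0 || n == 0) return out;

  const int open_cost = gap_open + gap_extend;
  std::vector<int> Hrow(n + 1, 0), Erow(n + 1, INT32_MIN / 4);
  std::vector<int> Fcol(n + 1, INT32_MIN / 4);
  // traceback: 2 bits H-source (0 stop, 1 diag, 2 left/E, 3 up/F),
  // bit2: E extended from E, bit3: F extended from F
  std::vector<uint8_t> tb(static_cast<size_t>(m) * n, 0);

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    int Hdiag = 0;  // H[i-1][0]
    Hrow[0] = 0;
    int E = INT32_MIN / 4;  // E[i][0]
    for (int j = 1; j <= n; ++j) {
      uint8_t t = 0;
      // Hrow[j-1] already holds H[i][j-1] (updated earlier this row);
      // Hrow[j] still holds H[i-1][j]
      int e_open = Hrow[j - 1] - open_cost;
      int e_ext = E - gap_extend;
      if (e_ext > e_open) { E = e_ext; t |= 4; } else { E = e_open; }
      int f_open = Hrow[j] - open_cost;  // Hrow[j] still holds H[i-1][j]
      int f_ext = Fcol[j] - gap_extend;
      int F;
      if (f_ext > f_open) { F = f_ext; t |= 8; } else { F = f_open; }
      Fcol[j] = F;
      int diag = Hdiag + (q[i - 1] == s[j - 1] ? match : -mismatch);
      int h = 0; uint8_t src = 0;
      if (diag > h) { h = diag; src = 1; }
      if (F > h) { h = F; src = 3; }
      if (E > h) { h = E; src = 2; }
      Hdiag = Hrow[j];
      Hrow[j] = h;
      tb[static_cast<size_t>(i - 1) * n + (j - 1)] = t | src;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  if (best <= 0) return out;

  // traceback from (bi, bj)
  int i = bi, j = bj;
  bool in_gapq = false, in_gaps = false;
  out.score = best;
  out.qend = bi; out.send = bj;
  while (i > 0 && j > 0) {
    uint8_t t = tb[static_cast<size_t>(i - 1) * n + (j - 1)];
    uint8_t src = t & 3;
    if (src == 0) break;
    if (src == 1) {
      ++out.length;
      if (q[i - 1] == s[j - 1]) ++out.matches; else ++out.mismatch;
      in_gapq = in_gaps = false;
      --i; --j;
    } else if (src == 2) {
      // gap in query (consume subject)
      while (true) {
        ++out.length;
        if (!in_gapq) { ++out.gapopen; in_gapq = true; }
        bool ext = (tb[static_cast<size_t>(i - 1) * n + (j - 1)] & 4) != 0;
        --j;
        if (!ext || j == 0) break;
      }
      in_gaps = false;
    } else {
      // gap in subject (consume query)
      while (true) {
        ++out.length;
        if (!in_gaps) { ++out.gapopen; in_gaps = true; }
        bool ext = (tb[static_cast<size_t>(i - 1) * n + (j - 1)] & 8) != 0;
        --i;
        if (!ext || i == 0) break;
      }
      in_gapq = false;
    }
  }
  out.qstart = i + 1;
  out.sstart = j + 1;
  return out;
}

inline bool pack_kmer(const std::string& s, int pos, int k, uint64_t& out) {
  uint64_t v = 0;
  for (int i = 0; i < k; ++i) {
    int c = nt_code(s[pos + i]);
    if (c < 0) return false;
    v = (v << 2) | static_cast<uint64_t>(c);
  }
  out = v;
  return true;
}

// best ungapped score on one diagonal (Kadane over +match/-mismatch)
int diag_ungapped(const std::string& q, const std::string& s, int diag,
                  int match, int mismatch) {
  // diag = spos - qpos (0-based)
  int qi = diag < 0 ? -diag : 0;
  int sj = diag < 0 ? 0 : diag;
  int best = 0, run = 0;
  const int m = static_cast<int>(q.size());
  const int n = static_cast<int>(s.size());
  while (qi < m && sj < n) {
    run += (q[qi] == s[sj]) ? match : -mismatch;
    if (run < 0) run = 0;
    if (run > best) best = run;
    ++qi; ++sj;
  }
  return best;
}

}  // namespace

// Number of k-mer postings each sequence contributes: max(0, L - k + 1)
// counting only windows over A/C/G/T.
// [[Rcpp::export]]
IntegerVector cl_kmer_postings(CharacterVector seqs, int k) {
  IntegerVector out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    int cnt = 0;
    uint64_t v;
    for (int p = 0; p + k <= static_cast<int>(s.size()); ++p)
      if (pack_kmer(s, p, k, v)) ++cnt;
    out[i] = cnt;
  }
  return out;
}

// Full local alignment of one pair; returns named integer vector of stats.
// [[Rcpp::export]]
IntegerVector cl_sw_pair(std::string q, std::string s, int match, int mismatch,
                         int gap_open, int gap_extend) {
  AlnStats a = sw_align(q, s, match, mismatch, gap_open, gap_extend);
  return IntegerVector::create(
      _["score"] = a.score, _["length"] = a.length, _["matches"] = a.matches,
      _["mismatch"] = a.mismatch, _["gapopen"] = a.gapopen,
      _["qstart"] = a.qstart, _["qend"] = a.qend, _["sstart"] = a.sstart,
      _["send"] = a.send);
}

// Batch alignment: queries (subset given by 1-based query_idx) against the
// subject set. Seeding with exact k-mers; subjects sharing >= min_seed k-mers
// with the query are ranked by seed support and the top max_candidates are
// screened by best-diagonal ungapped score >= gate before the full gapped
// alignment is run.
// [[Rcpp::export]]
List cl_align_batch(CharacterVector qseqs, CharacterVector sseqs,
                    IntegerVector query_idx, int k, int min_seed, int gate,
                    int max_candidates, int match, int mismatch, int gap_open,
                    int gap_extend) {
  const int ns = static_cast<int>(sseqs.size());
  std::vector<std::string> subj(ns);
  for (int i = 0; i < ns; ++i) subj[i] = as<std::string>(sseqs[i]);

  // k-mer -> postings (subject index, offset)
  std::unordered_map<uint64_t, std::vector<std::pair<int, int>>> index;
  index.reserve(1 << 16);
  for (int i = 0; i < ns; ++i) {
    const std::string& s = subj[i];
    uint64_t v;
    for (int p = 0; p + k <= static_cast<int>(s.size()); ++p)
      if (pack_kmer(s, p, k, v)) index[v].emplace_back(i, p);
  }

  std::vector<int> r_q, r_s, r_score, r_len, r_matches, r_mm, r_go, r_qs,
      r_qe, r_ss, r_se;

  std::unordered_map<int64_t, int> diag_counts;
  std::unordered_map<int, int> totals;
  const int64_t DIAG_OFF = 1 << 20;

  for (R_xlen_t qq = 0; qq < query_idx.size(); ++qq) {
    const int qi = query_idx[qq] - 1;
    std::string q = as<std::string>(qseqs[qi]);
    const int qlen = static_cast<int>(q.size());
    if (qlen < k) continue;
    diag_counts.clear();
    totals.clear();
    uint64_t v;
    for (int p = 0; p + k <= qlen; ++p) {
      if (!pack_kmer(q, p, k, v)) continue;
      auto it = index.find(v);
      if (it == index.end()) continue;
      for (const auto& post : it->second) {
        int64_t key = static_cast<int64_t>(post.first) * (2 * DIAG_OFF) +
                      (post.second - p + DIAG_OFF);
        ++diag_counts[key];
        ++totals[post.first];
      }
    }
    // best diagonal per candidate subject
    std::unordered_map<int, std::pair<int, int>> best_diag;  // sidx -> (count, diag)
    for (const auto& kv : diag_counts) {
      int sidx = static_cast<int>(kv.first / (2 * DIAG_OFF));
      int diag = static_cast<int>(kv.first % (2 * DIAG_OFF)) - DIAG_OFF;
      auto& cur = best_diag[sidx];
      if (kv.second > cur.first) cur = {kv.second, diag};
    }
    // rank candidates by seed support (desc), subject index tie-break, and
    // keep at most max_candidates per query
    std::vector<std::pair<int, int>> ranked;  // (-count, sidx)
    for (const auto& kv : totals)
      if (kv.second >= min_seed) ranked.emplace_back(-kv.second, kv.first);
    std::sort(ranked.begin(), ranked.end());
    if (max_candidates > 0 &&
        static_cast<int>(ranked.size()) > max_candidates)
      ranked.resize(max_candidates);
    std::vector<int> cands;
    for (const auto& rc : ranked) cands.push_back(rc.second);
    std::sort(cands.begin(), cands.end());
    for (int sidx : cands) {
      const std::string& s = subj[sidx];
      int ug = diag_ungapped(q, s, best_diag[sidx].second, match, mismatch);
      if (ug < gate) continue;
      AlnStats a = sw_align(q, s, match, mismatch, gap_open, gap_extend);
      if (a.score <= 0) continue;
      r_q.push_back(qi + 1); r_s.push_back(sidx + 1);
      r_score.push_back(a.score); r_len.push_back(a.length);
      r_matches.push_back(a.matches); r_mm.push_back(a.mismatch);
      r_go.push_back(a.gapopen); r_qs.push_back(a.qstart);
      r_qe.push_back(a.qend); r_ss.push_back(a.sstart);
      r_se.push_back(a.send);
    }
  }

  return List::create(
      _["qidx"] = wrap(r_q), _["sidx"] = wrap(r_s), _["score"] = wrap(r_score),
      _["length"] = wrap(r_len), _["matches"] = wrap(r_matches),
      _["mismatch"] = wrap(r_mm), _["gapopen"] = wrap(r_go),
      _["qstart"] = wrap(r_qs), _["qend"] = wrap(r_qe),
      _["sstart"] = wrap(r_ss), _["send"] = wrap(r_se));
}
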