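// Core sequence machinery: 2-bit canonical k-mer index, anchor matching,
// co-linear chain DP, banded affine alignment (global / glocal / local),
// short-read best-hit mapping, and RNG helpers that draw from R's stream so
// set.seed() governs everything.
#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <algorithm>
#include <limits>
#include <vector>
#include <string>

using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
  }
  return -1;
}
static const char BASES[4] = {'A', 'C', 'G', 'T'};

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) {
    switch (c) {
      case 'A': c = 'T'; break; case 'T': c = 'A'; break;
      case 'C': c = 'G'; break; case 'G': c = 'C'; break;
      default: c = 'N';
    }
  }
  return r;
}

// ---------------------------------------------------------------------------
// k-mer index
// ---------------------------------------------------------------------------

struct GenomeIndex {
  int k;
  std::vector<std::string> names;
  std::vector<std::string> seqs;  // uppercase
  // entries grouped by canonical k-mer
  std::vector<uint32_t> e_chrom;
  std::vector<uint32_t> e_pos;
  std::vector<uint8_t>  e_fwd;    // 1 if forward k-mer at pos is the canonical one
  std::unordered_map<uint64_t, std::pair<uint32_t, uint32_t>> lookup;  // kmer -> (start, count)
};

// Rolling scan of canonical k-mers. cb(pos, canon, fwd) for each valid window.
template <typename F>
static void scan_kmers(const std::string& s, int k, F cb) {
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t fk = 0, rk = 0;
  int run = 0;
  const int shift = 2 * (k - 1);
  for (size_t i = 0; i < s.size(); ++i) {
    int c = base_code(s[i]);
    if (c < 0) { run = 0; fk = 0; rk = 0; continue; }
    fk = ((fk << 2) | (uint64_t)c) & mask;
    rk = (rk >> 2) | ((uint64_t)(3 - c) << shift);
    if (++run >= k) {
      size_t pos = i + 1 - k;
      bool fwd = fk <= rk;
      cb(pos, fwd ? fk : rk, fwd);
    }
  }
}

// [[Rcpp::export]]
SEXP cpp_build_index(CharacterVector seqs, CharacterVector names, int k) {
  if (k < 1 || k > 31) stop("k must be between 1 and 31");
  GenomeIndex* gi = new GenomeIndex();
  gi->k = k;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    gi->seqs.push_back(as<std::string>(seqs[i]));
    gi->names.push_back(as<std::string>(names[i]));
  }
  struct Rec { uint64_t kmer; uint32_t chrom; uint32_t pos; uint8_t fwd; };
  std::vector<Rec> recs;
  size_t total = 0;
  for (const auto& s : gi->seqs) if (s.size() >= (size_t)k) total += s.size() - k + 1;
  recs.reserve(total);
  for (size_t ci = 0; ci < gi->seqs.size(); ++ci) {
    scan_kmers(gi->seqs[ci], k, [&](size_t pos, uint64_t canon, bool fwd) {
      recs.push_back({canon, (uint32_t)ci, (uint32_t)pos, (uint8_t)(fwd ? 1 : 0)});
    });
  }
  std::sort(recs.begin(), recs.end(), [](const Rec& a, const Rec& b) {
    if (a.kmer != b.kmer) return a.kmer < b.kmer;
    if (a.chrom != b.chrom) return a.chrom < b.chrom;
    return a.pos < b.pos;
  });
  gi->e_chrom.reserve(recs.size());
  gi->e_pos.reserve(recs.size());
  gi->e_fwd.reserve(recs.size());
  gi->lookup.reserve(recs.size());
  for (size_t i = 0; i < recs.size();) {
    size_t j = i;
    while (j < recs.size() && recs[j].kmer == recs[i].kmer) ++j;
    gi->lookup.emplace(recs[i].kmer, std::make_pair((uint32_t)gi->e_pos.size(), (uint32_t)(j - i)));
    for (size_t t = i; t < j; ++t) {
      gi->e_chrom.push_back(recs[t].chrom);
      gi->e_pos.push_back(recs[t].pos);
      gi->e_fwd.push_back(recs[t].fwd);
    }
    i = j;
  }
  XPtr<GenomeIndex> ptr(gi, true);
  return ptr;
}

// [[Rcpp::export]]
List cpp_index_stats(SEXP xp) {
  XPtr<GenomeIndex> gi(xp);
  return List::create(_["n_positions"] = (double)gi->e_pos.size(),
                      _["n_distinct"] = (double)gi->lookup.size(),
                      _["k"] = gi->k);
}

// Decode the distinct canonical k-mers (small indexes only; for tests).
// [[Rcpp::export]]
CharacterVector cpp_index_kmers(SEXP xp) {
  XPtr<GenomeIndex> gi(xp);
  std::vector<std::string> out;
  out.reserve(gi->lookup.size());
  for (const auto& kv : gi->lookup) {
    std::string s(gi->k, 'A');
    uint64_t km = kv.first;
    for (int i = gi->k - 1; i >= 0; --i) { s[i] = BASES[km & 3]; km >>= 2; }
    out.push_back(s);
  }
  std::sort(out.begin(), out.end());
  return wrap(out);
}

// Number of k-mer windows of `seq` whose canonical form occurs in the index.
// [[Rcpp::export]]
int cpp_count_kmer_hits(SEXP xp, std::string seq) {
  XPtr<GenomeIndex> gi(xp);
  int n = 0;
  scan_kmers(seq, gi->k, [&](size_t, uint64_t canon, bool) {
    if (gi->lookup.count(canon)) ++n;
  });
  return n;
}

// ---------------------------------------------------------------------------
// anchors
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
DataFrame cpp_find_anchors(SEXP xp, CharacterVector qseqs, int max_occ) {
  XPtr<GenomeIndex> gi(xp);
  struct A { uint32_t tc, tp, qc, qp; int8_t st; };
  std::vector<A> out;
  for (R_xlen_t qi = 0; qi < qseqs.size(); ++qi) {
    std::string qs = as<std::string>(qseqs[qi]);
    scan_kmers(qs, gi->k, [&](size_t qpos, uint64_t canon, bool qfwd) {
      auto it = gi->lookup.find(canon);
      if (it == gi->lookup.end()) return;
      uint32_t start = it->second.first, cnt = it->second.second;
      if (max_occ > 0 && (int)cnt > max_occ) return;
      for (uint32_t e = start; e < start + cnt; ++e) {
        int8_t st = (gi->e_fwd[e] == (qfwd ? 1 : 0)) ? 1 : -1;
        out.push_back({gi->e_chrom[e], gi->e_pos[e], (uint32_t)qi, (uint32_t)qpos, st});
      }
    });
  }
  std::sort(out.begin(), out.end(), [](const A& a, const A& b) {
    if (a.tc != b.tc) return a.tc < b.tc;
    if (a.qc != b.qc) return a.qc < b.qc;
    if (a.st != b.st) return a.st > b.st;  // '+' before '-'
    if (a.tp != b.tp) return a.tp < b.tp;
    return a.qp < b.qp;
  });
  size_t n = out.size();
  IntegerVector tc(n), tp(n), qc(n), qp(n), st(n);
  for (size_t i = 0; i < n; ++i) {
    tc[i] = out[i].tc + 1; tp[i] = out[i].tp;
    qc[i] = out[i].qc + 1; qp[i] = out[i].qp;
    st[i] = out[i].st;
  }
  return DataFrame::create(_["t_chrom_i"] = tc, _["t_start"] = tp,
                           _["q_chrom_i"] = qc, _["q_start"] = qp,
                           _["strand_i"] = st);
}

// ---------------------------------------------------------------------------
// chaining
// ---------------------------------------------------------------------------

// Anchors of one (target chrom, query chrom, strand) group, sorted by
// (t, q); q already flipped to be co-increasing for minus-strand groups.
// Returns 0-based chain id per anchor, -1 if unchained.
// [[Rcpp::export]]
IntegerVector cpp_chain_anchors(IntegerVector t, IntegerVector q, int k,
                                int max_gap, int min_anchors, int max_drift) {
  int n = t.size();
  IntegerVector chain(n, -1);
  if (n == 0) return chain;
  std::vector<int> score(n, 1), prev(n, -1);
  for (int i = 0; i < n; ++i) {
    for (int j = i - 1; j >= 0; --j) {
      if (t[i] - t[j] - k > max_gap) break;
      if (t[j] >= t[i] || q[j] >= q[i]) continue;
      if (q[i] - q[j] - k > max_gap) continue;
      if (std::abs((t[i] - t[j]) - (q[i] - q[j])) > max_drift) continue;
      if (score[j] + 1 > score[i]) { score[i] = score[j] + 1; prev[i] = j; }
    }
  }
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (score[a] != score[b]) return score[a] > score[b];
    return a < b;
  });
  std::vector<char> used(n, 0);
  int next_id = 0;
  for (int s : ord) {
    if (used[s]) continue;
    std::vector<int> members;
    for (int cur = s; cur >= 0 && !used[cur]; cur = prev[cur]) {
      members.push_back(cur);
      used[cur] = 1;
    }
    if ((int)members.size() >= min_anchors) {
      for (int m : members) chain[m] = next_id;
      ++next_id;
    }
  }
  return chain;
}

// ---------------------------------------------------------------------------
// banded affine alignment
// ---------------------------------------------------------------------------
// Scoring: match +1, mismatch -1; a gap of length L costs gap_open + L*gap_ext
// (the Biostrings gapOpening/gapExtension convention).

struct AlnResult {
  int64_t score = 0, matches = 0, mismatches = 0, gapcols = 0;
  int bstart = 0, bend = 0;
  bool ok = false;
};

static AlnResult banded_align(const std::string& A, const std::string& B,
                              int extra, bool free_b_ends,
                              int match, int mismatch, int gap_open, int gap_ext) {
  AlnResult res;
  typedef int32_t sc_t;
  const sc_t NEG = std::numeric_limits<sc_t>::min() / 4;
  const int m = (int)A.size(), n = (int)B.size();
  const int lo = std::min(0, n - m) - extra;
  const int hi = std::max(0, n - m) + extra;
  const int W = hi - lo + 1;
  if (m == 0 || n == 0) return res;

  static thread_local std::vector<sc_t> M0v, X0v, Y0v, M1v, X1v, Y1v;
  static thread_local std::vector<uint8_t> tbv;
  M0v.assign(W, NEG); X0v.assign(W, NEG); Y0v.assign(W, NEG);
  M1v.assign(W, NEG); X1v.assign(W, NEG); Y1v.assign(W, NEG);
  tbv.assign((size_t)(m + 1) * W, 0);
  std::vector<sc_t>& M0 = M0v; std::vector<sc_t>& X0 = X0v;
  std::vector<sc_t>& Y0 = Y0v; std::vector<sc_t>& M1 = M1v;
  std::vector<sc_t>& X1 = X1v; std::vector<sc_t>& Y1 = Y1v;
  std::vector<uint8_t>& tb = tbv;

  // row 0
  for (int c = 0; c < W; ++c) {
    int j = 0 + lo + c;
    if (j < 0 || j > n) continue;
    if (j == 0) M0[c] = 0;
    else if (free_b_ends) M0[c] = 0;
    else X0[c] = -(sc_t)(gap_open + (int64_t)j * gap_ext);
  }

  for (int i = 1; i <= m; ++i) {
    std::fill(M1.begin(), M1.end(), NEG);
    std::fill(X1.begin(), X1.end(), NEG);
    std::fill(Y1.begin(), Y1.end(), NEG);
    uint8_t* tbrow = &tb[(size_t)i * W];
    for (int c = 0; c < W; ++c) {
      int j = i + lo + c;
      if (j < 0 || j > n) continue;
      uint8_t t = 0;
      // M: diagonal from (i-1, j-1) = previous row, same band column
      if (j >= 1) {
        sc_t best = M0[c]; int src = 0;
        if (X0[c] > best) { best = X0[c]; src = 1; }
        if (Y0[c] > best) { best = Y0[c]; src = 2; }
        if (best > NEG / 2) {
          char a = A[i - 1], b = B[j - 1];
          bool is_match = (a == b) && base_code(a) >= 0;
          M1[c] = best + (is_match ? match : -std::abs(mismatch));
          t |= (uint8_t)src;
        } else t |= 3;
      } else t |= 3;
      // X: gap in A, from (i, j-1) = same row, left band column
      if (c >= 1 && j >= 1) {
        sc_t fromM = (M1[c - 1] > NEG / 2) ? M1[c - 1] - (gap_open + gap_ext) : NEG;
        sc_t fromX = (X1[c - 1] > NEG / 2) ? X1[c - 1] - gap_ext : NEG;
        if (fromX > fromM) { X1[c] = fromX; t |= 4; }
        else if (fromM > NEG / 2) X1[c] = fromM;
      }
      // Y: gap in B, from (i-1, j) = previous row, right band column
      if (c + 1 < W) {
        sc_t fromM = (M0[c + 1] > NEG / 2) ? M0[c + 1] - (gap_open + gap_ext) : NEG;
        sc_t fromY = (Y0[c + 1] > NEG / 2) ? Y0[c + 1] - gap_ext : NEG;
        if (fromY > fromM) { Y1[c] = fromY; t |= 8; }
        else if (fromM > NEG / 2) Y1[c] = fromM;
      }
      tbrow[c] = t;
    }
    std::swap(M0, M1); std::swap(X0, X1); std::swap(Y0, Y1);
  }

  // pick endpoint
  int cend = -1, state = -1;  // 0=M 1=X 2=Y
  sc_t best = NEG;
  if (free_b_ends) {
    for (int c = 0; c < W; ++c) {
      int j = m + lo + c;
      if (j < 0 || j > n) continue;
      if (M0[c] > best) { best = M0[c]; cend = c; state = 0; }
      if (X0[c] > best) { best = X0[c]; cend = c; state = 1; }
      if (Y0[c] > best) { best = Y0[c]; cend = c; state = 2; }
    }
  } else {
    int c = n - m - lo;
    if (c >= 0 && c < W) {
      if (M0[c] > best) { best = M0[c]; cend = c; state = 0; }
      if (X0[c] > best) { best = X0[c]; cend = c; state = 1; }
      if (Y0[c] > best) { best = Y0[c]; cend = c; state = 2; }
    }
  }
  if (cend < 0 || best <= NEG / 2) return res;

  res.score = best;
  res.bend = m + lo + cend;
  // traceback
  int i = m, c = cend, st = state;
  while (true) {
    int j = i + lo + c;
    if (i == 0) {
      if (st == 0) { res.bstart = j; break; }
      if (st == 1) {  // leading gap in A consuming B (global mode)
        if (free_b_ends) { res.bstart = j; break; }
        res.gapcols += j; res.bstart = 0; break;
      }
      break;  // state Y at i==0 cannot occur
    }
    uint8_t t = tb[(size_t)i * W + c];
    if (st == 0) {
      int j1 = j;  // consumed A[i-1], B[j1-1]
      char a = A[i - 1], b = B[j1 - 1];
      if (a == b && base_code(a) >= 0) ++res.matches; else ++res.mismatches;
      int src = t & 3;
      --i;  // same c: j decreases by 1
      st = (src == 3) ? 0 : src;
    } else if (st == 1) {
      ++res.gapcols;
      st = (t & 4) ? 1 : 0;
      --c;
    } else {
      ++res.gapcols;
      st = (t & 8) ? 2 : 0;
      --i; ++c;
    }
  }
  res.ok = true;
  return res;
}

// [[Rcpp::export]]
List cpp_banded_align(std::string a, std::string b, int extra, bool free_b_ends,
                      int match, int mismatch, int gap_open, int gap_ext) {
  AlnResult r = banded_align(a, b, extra, free_b_ends, match, mismatch, gap_open, gap_ext);
  return List::create(_["ok"] = r.ok, _["score"] = (double)r.score,
                      _["matches"] = (double)r.matches,
                      _["mismatches"] = (double)r.mismatches,
                      _["gap_columns"] = (double)r.gapcols,
                      _["columns"] = (double)(r.matches + r.mismatches + r.gapcols),
                      _["b_start"] = r.bstart, _["b_end"] = r.bend);
}

// Banded local (Smith-Waterman) score only; band on diagonals j - i in [lo, hi].
static int64_t banded_local_score(const std::string& A, const std::string& B,
                                  int lo, int hi, int match, int mismatch,
                                  int gap_open, int gap_ext) {
  const int64_t NEG = std::numeric_limits<int64_t>::min() / 4;
  const int m = (int)A.size(), n = (int)B.size();
  const int W = hi - lo + 1;
  if (W <= 0 || m == 0 || n == 0) return 0;
  std::vector<int64_t> M0(W, NEG), X0(W, NEG), Y0(W, NEG), M1(W), X1(W), Y1(W);
  for (int c = 0; c < W; ++c) { int j = lo + c; if (j >= 0 && j <= n) M0[c] = 0; }
  int64_t best = 0;
  for (int i = 1; i <= m; ++i) {
    std::fill(M1.begin(), M1.end(), NEG);
    std::fill(X1.begin(), X1.end(), NEG);
    std::fill(Y1.begin(), Y1.end(), NEG);
    for (int c = 0; c < W; ++c) {
      int j = i + lo + c;
      if (j < 1 || j > n) { if (j == 0) M1[c] = 0; continue; }
      int64_t diag = std::max(std::max(M0[c], X0[c]), Y0[c]);
      char a = A[i - 1], b = B[j - 1];
      bool is_match = (a == b) && base_code(a) >= 0;
      int64_t sub = is_match ? match : -std::abs(mismatch);
      M1[c] = std::max((int64_t)0, (diag > NEG / 2 ? diag + sub : (int64_t)0 + sub));
      if (M1[c] < 0) M1[c] = 0;
      if (c >= 1) {
        int64_t fm = (M1[c - 1] > NEG / 2) ? M1[c - 1] - (gap_open + gap_ext) : NEG;
        int64_t fx = (X1[c - 1] > NEG / 2) ? X1[c - 1] - gap_ext : NEG;
        X1[c] = std::max(fm, fx);
      }
      if (c + 1 < W) {
        int64_t fm = (M0[c + 1] > NEG / 2) ? M0[c + 1] - (gap_open + gap_ext) : NEG;
        int64_t fy = (Y0[c + 1] > NEG / 2) ? Y0[c + 1] - gap_ext : NEG;
        Y1[c] = std::max(fm, fy);
      }
      if (M1[c] > best) best = M1[c];
    }
    std::swap(M0, M1); std::swap(X0, X1); std::swap(Y0, Y1);
  }
  return best;
}

// ---------------------------------------------------------------------------
// read mapping
// ---------------------------------------------------------------------------

// Best-hit glocal mapping of each read against the indexed genome.
// Seeds are canonical k-mer matches voting for (chrom, strand, diagonal);
// the top-voted candidate loci are extended with banded alignment in which the
// read is aligned end-to-end and the target window's ends are free.
// [[Rcpp::export]]
DataFrame cpp_align_reads(SEXP xp, CharacterVector reads, int pad, int extra,
                          int min_score, int max_occ, int max_candidates,
                          int match, int mismatch, int gap_open, int gap_ext) {
  XPtr<GenomeIndex> gi(xp);
  const int k = gi->k;
  std::vector<int> o_read, o_chrom, o_start, o_end, o_strand, o_alen;
  std::vector<double> o_matches, o_cols, o_ident, o_score;

  std::unordered_map<int64_t, int> votes;
  struct Cand { int chrom, strand; int64_t diag; int v; };

  for (R_xlen_t ri = 0; ri < reads.size(); ++ri) {
    std::string rd = as<std::string>(reads[ri]);
    const int len = (int)rd.size();
    if (len < k) continue;
    votes.clear();
    scan_kmers(rd, k, [&](size_t qpos, uint64_t canon, bool qfwd) {
      auto it = gi->lookup.find(canon);
      if (it == gi->lookup.end()) return;
      uint32_t start = it->second.first, cnt = it->second.second;
      if (max_occ > 0 && (int)cnt > max_occ) return;
      for (uint32_t e = start; e < start + cnt; ++e) {
        int strand = (gi->e_fwd[e] == (qfwd ? 1 : 0)) ? 1 : -1;
        int64_t diag = (strand == 1)
          ? (int64_t)gi->e_pos[e] - (int64_t)qpos
          : (int64_t)gi->e_pos[e] - (int64_t)(len - k - qpos);
        int64_t key = ((int64_t)gi->e_chrom[e] << 44) |
                      ((int64_t)(strand == 1 ? 0 : 1) << 43) |
                      (diag + ((int64_t)1 << 40));
        ++votes[key];
      }
    });
    if (votes.empty()) continue;
    std::vector<Cand> cands;
    cands.reserve(votes.size());
    for (const auto& kv : votes) {
      int chrom = (int)(kv.first >> 44);
      int strand = ((kv.first >> 43) & 1) ? -1 : 1;
      int64_t diag = (kv.first & (((int64_t)1 << 43) - 1)) - ((int64_t)1 << 40);
      cands.push_back({chrom, strand, diag, kv.second});
    }
    std::sort(cands.begin(), cands.end(), [](const Cand& a, const Cand& b) {
      if (a.v != b.v) return a.v > b.v;
      if (a.chrom != b.chrom) return a.chrom < b.chrom;
      if (a.strand != b.strand) return a.strand > b.strand;
      return a.diag < b.diag;
    });
    // de-duplicate nearby diagonals on the same chrom/strand; when one locus
    // dominates the seed votes, single-seed loci are random 15-mer collisions
    // and cannot carry the best alignment, so skip extending them
    int vmax = 0;
    for (const auto& c : cands) vmax = std::max(vmax, c.v);
    std::vector<Cand> picked;
    for (const auto& c : cands) {
      if (vmax >= 4 && c.v == 1) continue;
      bool dup = false;
      for (const auto& p : picked)
        if (p.chrom == c.chrom && p.strand == c.strand &&
            std::llabs(p.diag - c.diag) <= 2 * pad) { dup = true; break; }
      if (!dup) picked.push_back(c);
      if ((int)picked.size() >= max_candidates) break;
    }
    std::string rc;
    bool have = false;
    AlnResult bestr; int bchrom = -1, bstrand = 0; int64_t bws = 0;
    double bident = -1;
    for (const auto& c : picked) {
      const std::string& tgt = gi->seqs[c.chrom];
      int64_t ws = c.diag - pad, we = c.diag + len + pad;
      if (ws < 0) ws = 0;
      if (we > (int64_t)tgt.size()) we = tgt.size();
      if (we - ws < k) continue;
      std::string window = tgt.substr(ws, we - ws);
      const std::string& q = (c.strand == 1) ? rd : (rc.empty() ? (rc = revcomp(rd)) : rc);
      AlnResult r = banded_align(q, window, extra, true, match, mismatch, gap_open, gap_ext);
      if (!r.ok || r.score < min_score) continue;
      double ident = 100.0 * (double)r.matches /
                     (double)(r.matches + r.mismatches + r.gapcols);
      bool better = false;
      if (!have) better = true;
      else if (r.score != bestr.score) better = r.score > bestr.score;
      else if (ident != bident) better = ident > bident;
      else if (gi->names[c.chrom] != gi->names[bchrom]) better = gi->names[c.chrom] < gi->names[bchrom];
      else better = (ws + r.bstart) < (bws + bestr.bstart);
      if (better) { have = true; bestr = r; bchrom = c.chrom; bstrand = c.strand; bws = ws; bident = ident; }
    }
    if (!have) continue;
    o_read.push_back((int)ri + 1);
    o_chrom.push_back(bchrom + 1);
    o_start.push_back((int)(bws + bestr.bstart));
    o_end.push_back((int)(bws + bestr.bend));
    o_strand.push_back(bstrand);
    o_alen.push_back(len);
    o_matches.push_back((double)bestr.matches);
    o_cols.push_back((double)(bestr.matches + bestr.mismatches + bestr.gapcols));
    o_ident.push_back(bident);
    o_score.push_back((double)bestr.score);
  }
  return DataFrame::create(_["read_i"] = o_read, _["chrom_i"] = o_chrom,
                           _["t_start"] = o_start, _["t_end"] = o_end,
                           _["strand_i"] = o_strand, _["aligned_length"] = o_alen,
                           _["matches"] = o_matches, _["columns"] = o_cols,
                           _["identity"] = o_ident, _["score"] = o_score);
}

// All seed-supported loci of `seq` against the index scoring >= min_score by
// banded local alignment. Hit intervals are the seed-cluster extents.
// [[Rcpp::export]]
DataFrame cpp_find_all_hits(SEXP xp, std::string seq, int min_score, int extra,
                            int cluster_gap, int max_occ,
                            int match, int mismatch, int gap_open, int gap_ext) {
  XPtr<GenomeIndex> gi(xp);
  const int k = gi->k;
  const int len = (int)seq.size();
  struct Seed { int chrom, strand; int64_t diag, tpos; };
  std::vector<Seed> seeds;
  scan_kmers(seq, k, [&](size_t qpos, uint64_t canon, bool qfwd) {
    auto it = gi->lookup.find(canon);
    if (it == gi->lookup.end()) return;
    uint32_t start = it->second.first, cnt = it->second.second;
    if (max_occ > 0 && (int)cnt > max_occ) return;
    for (uint32_t e = start; e < start + cnt; ++e) {
      int strand = (gi->e_fwd[e] == (qfwd ? 1 : 0)) ? 1 : -1;
      int64_t diag = (strand == 1)
        ? (int64_t)gi->e_pos[e] - (int64_t)qpos
        : (int64_t)gi->e_pos[e] - (int64_t)(len - k - qpos);
      seeds.push_back({(int)gi->e_chrom[e], strand, diag, (int64_t)gi->e_pos[e]});
    }
  });
  std::vector<int> h_chrom, h_start, h_end, h_strand, h_nseeds;
  std::vector<double> h_score;
  if (!seeds.empty()) {
    std::sort(seeds.begin(), seeds.end(), [](const Seed& a, const Seed& b) {
      if (a.chrom != b.chrom) return a.chrom < b.chrom;
      if (a.strand != b.strand) return a.strand > b.strand;
      if (a.diag != b.diag) return a.diag < b.diag;
      return a.tpos < b.tpos;
    });
    size_t i = 0;
    std::string rc;
    while (i < seeds.size()) {
      size_t j = i + 1;
      while (j < seeds.size() && seeds[j].chrom == seeds[i].chrom &&
             seeds[j].strand == seeds[i].strand &&
             seeds[j].diag - seeds[j - 1].diag <= cluster_gap) ++j;
      int64_t tmin = seeds[i].tpos, tmax = seeds[i].tpos;
      int64_t dmin = seeds[i].diag, dmax = seeds[j - 1].diag;
      for (size_t t = i; t < j; ++t) {
        tmin = std::min(tmin, seeds[t].tpos);
        tmax = std::max(tmax, seeds[t].tpos);
      }
      const std::string& tgt = gi->seqs[seeds[i].chrom];
      int64_t ws = tmin - extra - k, we = tmax + k + extra + k;
      if (ws < 0) ws = 0;
      if (we > (int64_t)tgt.size()) we = tgt.size();
      std::string window = tgt.substr(ws, we - ws);
      const std::string& q = (seeds[i].strand == 1) ? seq
                              : (rc.empty() ? (rc = revcomp(seq)) : rc);
      // band on diagonals relative to the window
      int64_t dlo, dhi;
      if (seeds[i].strand == 1) { dlo = dmin - ws - extra; dhi = dmax - ws + extra; }
      else {
        // rc query position q' = len - k - q; diag was computed for rc already
        dlo = dmin - ws - extra; dhi = dmax - ws + extra;
      }
      int64_t sc = banded_local_score(q, window, (int)dlo, (int)dhi,
                                      match, mismatch, gap_open, gap_ext);
      if (sc >= min_score) {
        h_chrom.push_back(seeds[i].chrom + 1);
        h_start.push_back((int)tmin);
        h_end.push_back((int)(tmax + k));
        h_strand.push_back(seeds[i].strand);
        h_nseeds.push_back((int)(j - i));
        h_score.push_back((double)sc);
      }
      i = j;
    }
  }
  return DataFrame::create(_["chrom_i"] = h_chrom, _["start"] = h_start,
                           _["end"] = h_end, _["strand_i"] = h_strand,
                           _["n_seeds"] = h_nseeds, _["score"] = h_score);
}

// ---------------------------------------------------------------------------
// simulation helpers (R RNG)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
std::string cpp_random_seq(int n, double gc) {
  std::string s(n, 'A');
  double half_gc = gc / 2.0, half_at = (1.0 - gc) / 2.0;
  for (int i = 0; i < n; ++i) {
    double u = unif_rand();
    if (u < half_at) s[i] = 'A';
    else if (u < 2 * half_at) s[i] = 'T';
    else if (u < 2 * half_at + half_gc) s[i] = 'G';
    else s[i] = 'C';
  }
  return s;
}

// Uniform site choice, uniform alternative base (Jukes-Cantor-like).
// [[Rcpp::export]]
List cpp_mutate_substitutions(std::string seq, double rate) {
  int n_sub = 0;
  for (size_t i = 0; i < seq.size(); ++i) {
    int c = base_code(seq[i]);
    if (c < 0) continue;
    if (unif_rand() < rate) {
      int alt = (int)(unif_rand() * 3.0);
      if (alt > 2) alt = 2;
      int nc = (c + 1 + alt) % 4;
      seq[i] = BASES[nc];
      ++n_sub;
    }
  }
  return List::create(_["seq"] = seq, _["n_substitutions"] = n_sub);
}

// [[Rcpp::export]]
CharacterVector cpp_apply_read_errors(CharacterVector seqs, double rate) {
  CharacterVector out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    for (size_t p = 0; p < s.size(); ++p) {
      int c = base_code(s[p]);
      if (c < 0) continue;
      if (unif_rand() < rate) {
        int alt = (int)(unif_rand() * 3.0);
        if (alt > 2) alt = 2;
        s[p] = BASES[(c + 1 + alt) % 4];
      }
    }
    out[i] = s;
  }
  return out;
}

// [[Rcpp::export]]
std::string cpp_revcomp(std::string s) { return revcomp(s); }
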