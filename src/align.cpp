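#include <Rcpp.h>
#include <unordered_map>
#include <map>
#include <set>
#include "seq_utils.h"

using namespace Rcpp;

namespace {

struct Block {
  int qs, qe, ts, te;  // 0-based half-open, same length (gapless diagonal)
  int match, mm;
  int score() const { return match - mm; }
};

// extend a diagonal run in both directions, tolerating isolated mismatches
// (at most 2 consecutive), then trim flanking mismatches
Block extend_block(const std::string &q, const std::string &t, int qs, int qe,
                   int diag) {
  int L = (int)q.size(), T = (int)t.size();
  // right extension
  int cm = 0, last_good = qe;
  int p = qe;
  while (p < L && p + diag < T) {
    if (q[p] == t[p + diag]) { cm = 0; last_good = p + 1; }
    else { if (++cm > 2) break; }
    ++p;
  }
  qe = last_good;
  // left extension
  cm = 0; int first_good = qs;
  p = qs - 1;
  while (p >= 0 && p + diag >= 0) {
    if (q[p] == t[p + diag]) { cm = 0; first_good = p; }
    else { if (++cm > 2) break; }
    --p;
  }
  qs = first_good;
  Block b;
  b.qs = qs; b.qe = qe; b.ts = qs + diag; b.te = qe + diag;
  b.match = 0; b.mm = 0;
  for (int i = qs; i < qe; ++i) {
    if (q[i] == t[i + diag]) ++b.match; else ++b.mm;
  }
  return b;
}

} // namespace

// Spliced-lite alignment of contigs against reference sequences: exact
// seed_k-mer anchors on both strands, diagonal blocks extended through
// isolated mismatches, then co-linear chaining with target gaps (introns)
// bounded by max_intron. Per contig, every chain attaining the maximum
// score s = matches - mismatches is reported. Query coordinates for '-'
// strand hits refer to the reverse-complemented query.
// [[Rcpp::export]]
List cpp_align_contigs(CharacterVector query_seqs, CharacterVector target_seqs,
                       int seed_k, int stride, int max_intron) {
  int nt = target_seqs.size();
  std::vector<std::string> targets(nt);
  std::unordered_map<std::string, std::vector<std::pair<int, int>>> index;
  for (int t = 0; t < nt; ++t) {
    targets[t] = as<std::string>(target_seqs[t]);
    const std::string &s = targets[t];
    if ((int)s.size() < seed_k) continue;
    for (size_t p = 0; p + seed_k <= s.size(); ++p) {
      if (!clean_kmer(s, p, seed_k)) continue;
      index[s.substr(p, seed_k)].push_back({t, (int)p});
    }
  }

  std::vector<int> o_query, o_target, o_matches, o_mm, o_score;
  std::vector<int> o_strand;
  std::vector<IntegerMatrix> o_blocks;

  int nq = query_seqs.size();
  for (int qi = 0; qi < nq; ++qi) {
    std::string fwd = as<std::string>(query_seqs[qi]);
    int L = (int)fwd.size();
    if (L < seed_k) continue;
    std::string rev = revcomp(fwd);

    struct Chain { int t, strand, score, matches, mm; std::vector<Block> blocks; };
    std::vector<Chain> chains;

    for (int strand = 0; strand < 2; ++strand) {
      const std::string &q = strand == 0 ? fwd : rev;
      // anchors per (target, diagonal)
      std::map<std::pair<int, int>, std::vector<int>> diag_hits;
      std::vector<int> offs;
      for (int o = 0; o + seed_k <= L; o += stride) offs.push_back(o);
      if (offs.empty() || offs.back() != L - seed_k) offs.push_back(L - seed_k);
      for (int o : offs) {
        if (!clean_kmer(q, o, seed_k)) continue;
        auto it = index.find(q.substr(o, seed_k));
        if (it == index.end()) continue;
        for (auto &loc : it->second)
          diag_hits[{loc.first, loc.second - o}].push_back(o);
      }
      // blocks per target
      std::map<int, std::vector<Block>> tblocks;
      for (auto &kv : diag_hits) {
        int t = kv.first.first, diag = kv.first.second;
        std::vector<int> &qs = kv.second;
        std::sort(qs.begin(), qs.end());
        Block b = extend_block(q, targets[t], qs.front(),
                               qs.back() + seed_k, diag);
        if (b.qe > b.qs) tblocks[t].push_back(b);
      }
      for (auto &kv : tblocks) {
        int t = kv.first;
        std::vector<Block> &bl = kv.second;
        // merge duplicate/contained blocks on the same target
        std::sort(bl.begin(), bl.end(), [](const Block &a, const Block &b) {
          if (a.qs != b.qs) return a.qs < b.qs;
          return a.score() > b.score();
        });
        std::vector<Block> uniq;
        for (auto &b : bl) {
          bool dup = false;
          for (auto &u : uniq)
            if (b.qs >= u.qs && b.qe <= u.qe && b.ts >= u.ts && b.te <= u.te) {
              dup = true; break;
            }
          if (!dup) uniq.push_back(b);
        }
        // co-linear chaining DP; extension creep may make neighboring
        // blocks overlap slightly in the query, so links tolerate a small
        // overlap which is trimmed exactly during chain reconstruction
        const int max_trim = 16;
        int n = (int)uniq.size();
        std::vector<int> dp(n), par(n, -1);
        for (int i = 0; i < n; ++i) dp[i] = uniq[i].score();
        for (int i = 0; i < n; ++i) {
          for (int j = 0; j < i; ++j) {
            int d = std::max(0, uniq[j].qe - uniq[i].qs);
            if (d > max_trim) continue;
            if (uniq[i].qe <= uniq[j].qe) continue;
            long tgap = (long)uniq[i].ts + d - uniq[j].te;
            if (tgap < 0 || tgap > max_intron) continue;
            int s = dp[j] + uniq[i].score() - d;
            if (s > dp[i]) { dp[i] = s; par[i] = j; }
          }
        }
        if (n == 0) continue;
        int best_dp = dp[0];
        for (int i = 1; i < n; ++i) best_dp = std::max(best_dp, dp[i]);
        // every chain attaining the best raw score is reconstructed (a
        // contig with several equally scoring loci keeps all of them)
        auto rescore = [&](Block &b) {
          b.match = 0; b.mm = 0;
          int diag = b.ts - b.qs;
          for (int p = b.qs; p < b.qe; ++p) {
            if (q[p] == targets[t][p + diag]) ++b.match; else ++b.mm;
          }
        };
        for (int bi = 0; bi < n; ++bi) {
          if (dp[bi] != best_dp) continue;
          std::vector<Block> chain;
          for (int i = bi; i >= 0; i = par[i]) chain.push_back(uniq[i]);
          std::reverse(chain.begin(), chain.end());
          // resolve query overlaps between adjacent blocks at the split
          // point that maximizes the number of matching bases
          for (size_t i = 1; i < chain.size(); ++i) {
            Block &a = chain[i - 1], &b = chain[i];
            if (b.qs < a.qe) {
              int lo = b.qs, hi = a.qe;
              int da = a.ts - a.qs, db = b.ts - b.qs;
              int best_s = hi, best_gain = -1;
              for (int s = lo; s <= hi; ++s) {
                int gain = 0;
                for (int p = lo; p < s; ++p)
                  if (q[p] == targets[t][p + da]) ++gain;
                for (int p = s; p < hi; ++p)
                  if (q[p] == targets[t][p + db]) ++gain;
                if (gain > best_gain) { best_gain = gain; best_s = s; }
              }
              a.qe = best_s; a.te = best_s + da;
              b.qs = best_s; b.ts = best_s + db;
              rescore(a); rescore(b);
            }
          }
          Chain ch;
          ch.t = t; ch.strand = strand;
          ch.matches = 0; ch.mm = 0;
          for (auto &b : chain)
            if (b.qe > b.qs) {
              ch.blocks.push_back(b);
              ch.matches += b.match; ch.mm += b.mm;
            }
          if (ch.blocks.empty()) continue;
          ch.score = ch.matches - ch.mm;
          chains.push_back(ch);
        }
      }
    }
    if (chains.empty()) continue;
    int best = chains[0].score;
    for (auto &c : chains) best = std::max(best, c.score);
    for (auto &c : chains) {
      if (c.score != best) continue;
      IntegerMatrix bm((int)c.blocks.size(), 4);
      for (size_t i = 0; i < c.blocks.size(); ++i) {
        bm(i, 0) = c.blocks[i].qs; bm(i, 1) = c.blocks[i].qe;
        bm(i, 2) = c.blocks[i].ts; bm(i, 3) = c.blocks[i].te;
      }
      o_query.push_back(qi + 1);
      o_target.push_back(c.t + 1);
      o_strand.push_back(c.strand == 0 ? 1 : -1);
      o_matches.push_back(c.matches);
      o_mm.push_back(c.mm);
      o_score.push_back(c.score);
      o_blocks.push_back(bm);
    }
  }
  List blocks(o_blocks.size());
  for (size_t i = 0; i < o_blocks.size(); ++i) blocks[i] = o_blocks[i];
  return List::create(_["query"] = wrap(o_query), _["target"] = wrap(o_target),
                      _["strand"] = wrap(o_strand),
                      _["matches"] = wrap(o_matches),
                      _["mismatches"] = wrap(o_mm),
                      _["score"] = wrap(o_score), _["blocks"] = blocks);
}

// Suffix-prefix (dovetail) overlaps between contig pairs in either relative
// orientation. Overlap candidates are anchored on exact anchor_k-mers (the
// start of the incoming contig's prefix, or the end of the outgoing contig's
// suffix) and verified base-by-base; identity = matches / overlap_len.
// Reports, per ordered pair (i right-end joins j left-end, orientation of
// j), the longest overlap passing both thresholds.
// [[Rcpp::export]]
List cpp_find_overlaps(CharacterVector seqs, int min_overlap,
                       double min_identity, int anchor_k) {
  int n = seqs.size();
  std::vector<std::string> fw(n), rc(n);
  for (int i = 0; i < n; ++i) {
    fw[i] = as<std::string>(seqs[i]);
    rc[i] = revcomp(fw[i]);
  }
  // index over both orientations of every contig
  std::unordered_map<std::string, std::vector<std::tuple<int, int, int>>> idx;
  for (int i = 0; i < n; ++i) {
    for (int o = 0; o < 2; ++o) {
      const std::string &s = o == 0 ? fw[i] : rc[i];
      if ((int)s.size() < anchor_k) continue;
      for (size_t p = 0; p + anchor_k <= s.size(); ++p)
        idx[s.substr(p, anchor_k)].push_back({i, o, (int)p});
    }
  }
  // best candidate per (i, j, orient)
  std::map<std::tuple<int, int, int>, std::pair<int, int>> best;  // -> ov, matches
  auto consider = [&](int i, int j, int o, int ov) {
    if (i == j) return;
    const std::string &a = fw[i];
    const std::string &b = o == 0 ? fw[j] : rc[j];
    int la = (int)a.size(), lb = (int)b.size();
    if (ov < min_overlap || ov > la || ov > lb) return;
    int m = 0;
    for (int x = 0; x < ov; ++x)
      if (a[la - ov + x] == b[x]) ++m;
    if ((double)m / ov < min_identity) return;
    auto key = std::make_tuple(i, j, o);
    auto it = best.find(key);
    if (it == best.end() || ov > it->second.first ||
        (ov == it->second.first && m > it->second.second))
      best[key] = {ov, m};
  };
  for (int j = 0; j < n; ++j) {
    for (int o = 0; o < 2; ++o) {
      const std::string &b = o == 0 ? fw[j] : rc[j];
      if ((int)b.size() < anchor_k) continue;
      // anchor: first anchor_k of b found inside any a (forward orientation)
      auto it = idx.find(b.substr(0, anchor_k));
      if (it != idx.end()) {
        for (auto &loc : it->second) {
          if (std::get<1>(loc) != 0) continue;  // a in forward orientation
          int i = std::get<0>(loc), p = std::get<2>(loc);
          consider(i, j, o, (int)fw[i].size() - p);
        }
      }
    }
  }
  for (int i = 0; i < n; ++i) {
    const std::string &a = fw[i];
    if ((int)a.size() < anchor_k) continue;
    // anchor: last anchor_k of a found inside any b (either orientation)
    auto it = idx.find(a.substr(a.size() - anchor_k));
    if (it != idx.end()) {
      for (auto &loc : it->second) {
        int j = std::get<0>(loc), o = std::get<1>(loc), p = std::get<2>(loc);
        consider(i, j, o, p + anchor_k);
      }
    }
  }
  std::vector<int> oi, oj, oo, ov;
  std::vector<double> ident;
  std::vector<int> omatch;
  for (auto &kv : best) {
    oi.push_back(std::get<0>(kv.first) + 1);
    oj.push_back(std::get<1>(kv.first) + 1);
    oo.push_back(std::get<2>(kv.first));
    ov.push_back(kv.second.first);
    omatch.push_back(kv.second.second);
    ident.push_back((double)kv.second.second / kv.second.first);
  }
  return List::create(_["i"] = wrap(oi), _["j"] = wrap(oj),
                      _["orient"] = wrap(oo), _["overlap_len"] = wrap(ov),
                      _["matches"] = wrap(omatch), _["identity"] = wrap(ident));
}

// Exact containment pairs: (i, j) such that contig i (or its reverse
// complement) is an exact substring of contig j, i != j. Anchored on the
// first anchor_k-mer of i and verified.
// [[Rcpp::export]]
List cpp_containment_pairs(CharacterVector seqs, int anchor_k) {
  int n = seqs.size();
  std::vector<std::string> fw(n), rc(n);
  for (int i = 0; i < n; ++i) {
    fw[i] = as<std::string>(seqs[i]);
    rc[i] = revcomp(fw[i]);
  }
  std::unordered_map<std::string, std::vector<std::pair<int, int>>> idx;
  for (int j = 0; j < n; ++j) {
    const std::string &s = fw[j];
    if ((int)s.size() < anchor_k) continue;
    for (size_t p = 0; p + anchor_k <= s.size(); ++p)
      idx[s.substr(p, anchor_k)].push_back({j, (int)p});
  }
  std::set<std::pair<int, int>> pairs;
  for (int i = 0; i < n; ++i) {
    for (int o = 0; o < 2; ++o) {
      const std::string &q = o == 0 ? fw[i] : rc[i];
      if ((int)q.size() < anchor_k) continue;
      auto it = idx.find(q.substr(0, anchor_k));
      if (it == idx.end()) continue;
      for (auto &loc : it->second) {
        int j = loc.first, p = loc.second;
        if (j == i) continue;
        if (p + q.size() > fw[j].size()) continue;
        if (fw[j].compare(p, q.size(), q) == 0) pairs.insert({i, j});
      }
    }
  }
  std::vector<int> pi, pj;
  for (auto &pr : pairs) { pi.push_back(pr.first + 1); pj.push_back(pr.second + 1); }
  return List::create(_["i"] = wrap(pi), _["j"] = wrap(pj));
}
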