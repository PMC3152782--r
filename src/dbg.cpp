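#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include "seq_utils.h"

using namespace Rcpp;

// de Bruijn graph over k-mers: an edge is a k-mer with an occurrence count,
// connecting its (k-1)-prefix node to its (k-1)-suffix node.

namespace {

struct Graph {
  int k;
  std::vector<std::string> kmer;
  std::vector<double> count;
  std::vector<bool> alive;
  // node -> edge indices
  std::unordered_map<std::string, std::vector<int>> out_e, in_e;

  void build_index() {
    out_e.clear(); in_e.clear();
    for (size_t i = 0; i < kmer.size(); ++i) {
      if (!alive[i]) continue;
      out_e[kmer[i].substr(0, k - 1)].push_back((int)i);
      in_e[kmer[i].substr(1)].push_back((int)i);
    }
  }
  int outdeg(const std::string &n) const {
    auto it = out_e.find(n);
    if (it == out_e.end()) return 0;
    int d = 0; for (int e : it->second) if (alive[e]) ++d;
    return d;
  }
  int indeg(const std::string &n) const {
    auto it = in_e.find(n);
    if (it == in_e.end()) return 0;
    int d = 0; for (int e : it->second) if (alive[e]) ++d;
    return d;
  }
  std::vector<int> out_edges(const std::string &n) const {
    std::vector<int> v;
    auto it = out_e.find(n);
    if (it != out_e.end()) for (int e : it->second) if (alive[e]) v.push_back(e);
    return v;
  }
  std::vector<int> in_edges(const std::string &n) const {
    std::vector<int> v;
    auto it = in_e.find(n);
    if (it != in_e.end()) for (int e : it->second) if (alive[e]) v.push_back(e);
    return v;
  }
};

Graph make_graph(CharacterVector kmers, NumericVector counts, int k) {
  Graph g;
  g.k = k;
  size_t n = kmers.size();
  g.kmer.reserve(n); g.count.reserve(n);
  for (size_t i = 0; i < n; ++i) {
    g.kmer.push_back(as<std::string>(kmers[i]));
    g.count.push_back(counts[i]);
  }
  g.alive.assign(n, true);
  g.build_index();
  return g;
}

List graph_to_list(const Graph &g) {
  std::vector<std::pair<std::string, double>> kept;
  for (size_t i = 0; i < g.kmer.size(); ++i)
    if (g.alive[i]) kept.push_back({g.kmer[i], g.count[i]});
  std::sort(kept.begin(), kept.end());
  CharacterVector km(kept.size());
  NumericVector ct(kept.size());
  for (size_t i = 0; i < kept.size(); ++i) {
    km[i] = kept[i].first; ct[i] = kept[i].second;
  }
  return List::create(_["kmer"] = km, _["count"] = ct);
}

} // namespace

// [[Rcpp::export]]
List cpp_build_graph(CharacterVector seqs, IntegerVector mult, int k,
                     bool both_strands) {
  std::unordered_map<std::string, double> tab;
  int n = seqs.size();
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    double w = (double)mult[i];
    if ((int)s.size() < k) continue;
    for (size_t p = 0; p + k <= s.size(); ++p) {
      if (!clean_kmer(s, p, k)) continue;
      tab[s.substr(p, k)] += w;
      if (both_strands) tab[revcomp(s.substr(p, k))] += w;
    }
  }
  std::vector<std::string> keys;
  keys.reserve(tab.size());
  for (auto &kv : tab) keys.push_back(kv.first);
  std::sort(keys.begin(), keys.end());
  NumericVector counts(keys.size());
  for (size_t i = 0; i < keys.size(); ++i) counts[i] = tab[keys[i]];
  return List::create(_["kmer"] = wrap(keys), _["count"] = counts);
}

// Remove dead-end branches (tips) of <= max_tip_len edges whose mean
// coverage is strictly below the strongest competing branch at their fork.
// Iterates to convergence, handling both out-tips and in-tips.
// [[Rcpp::export]]
List cpp_tip_clip(CharacterVector kmers, NumericVector counts, int k,
                  int max_tip_len) {
  Graph g = make_graph(kmers, counts, k);
  bool changed = true;
  while (changed) {
    changed = false;
    // collect candidate dead-end nodes deterministically
    std::vector<std::string> nodes;
    for (auto &kv : g.out_e) nodes.push_back(kv.first);
    for (auto &kv : g.in_e)
      if (g.out_e.find(kv.first) == g.out_e.end()) nodes.push_back(kv.first);
    std::sort(nodes.begin(), nodes.end());
    nodes.erase(std::unique(nodes.begin(), nodes.end()), nodes.end());
    for (const auto &start : nodes) {
      // out-tip: node with no outgoing edges, walk backwards to a fork
      if (g.outdeg(start) == 0 && g.indeg(start) >= 1) {
        std::vector<int> path;
        std::string v = start;
        while ((int)path.size() <= max_tip_len) {
          std::vector<int> ins = g.in_edges(v);
          if (ins.size() != 1) break;
          int e = ins[0];
          std::string u = g.kmer[e].substr(0, g.k - 1);
          path.push_back(e);
          if (g.outdeg(u) > 1) {
            if ((int)path.size() <= max_tip_len) {
              double tip_cov = 0;
              for (int pe : path) tip_cov += g.count[pe];
              tip_cov /= path.size();
              double comp = 0;
              for (int oe : g.out_edges(u))
                if (oe != path.back()) comp = std::max(comp, g.count[oe]);
              if (tip_cov < comp) {
                for (int pe : path) g.alive[pe] = false;
                changed = true;
              }
            }
            break;
          }
          if (g.indeg(u) != 1 || g.outdeg(u) != 1) break;
          v = u;
        }
      }
      // in-tip: node with no incoming edges, walk forwards to a fork
      if (g.indeg(start) == 0 && g.outdeg(start) >= 1) {
        std::vector<int> path;
        std::string v = start;
        while ((int)path.size() <= max_tip_len) {
          std::vector<int> outs = g.out_edges(v);
          if (outs.size() != 1) break;
          int e = outs[0];
          std::string u = g.kmer[e].substr(1);
          path.push_back(e);
          if (g.indeg(u) > 1) {
            if ((int)path.size() <= max_tip_len) {
              double tip_cov = 0;
              for (int pe : path) tip_cov += g.count[pe];
              tip_cov /= path.size();
              double comp = 0;
              for (int oe : g.in_edges(u))
                if (oe != path.back()) comp = std::max(comp, g.count[oe]);
              if (tip_cov < comp) {
                for (int pe : path) g.alive[pe] = false;
                changed = true;
              }
            }
            break;
          }
          if (g.indeg(u) != 1 || g.outdeg(u) != 1) break;
          v = u;
        }
      }
    }
    if (changed) g.build_index();
  }
  return graph_to_list(g);
}

// Maximal non-branching paths; unitigs with mean edge coverage < cov_cutoff
// are discarded. With canonical=true each unitig is reported in its
// lexicographically smaller orientation and exact duplicates are removed
// (used for double-stranded graphs).
// [[Rcpp::export]]
List cpp_extract_unitigs(CharacterVector kmers, NumericVector counts, int k,
                         double cov_cutoff, bool canonical) {
  Graph g = make_graph(kmers, counts, k);
  size_t ne = g.kmer.size();
  // deterministic edge order
  std::vector<int> order(ne);
  for (size_t i = 0; i < ne; ++i) order[i] = (int)i;
  std::sort(order.begin(), order.end(),
            [&](int a, int b) { return g.kmer[a] < g.kmer[b]; });
  std::vector<bool> used(ne, false);
  std::vector<std::string> seqs;
  std::vector<double> covs;
  std::vector<int> lens;

  auto walk = [&](int e0) {
    std::string u = g.kmer[e0].substr(0, g.k - 1);
    std::string seq = u;
    double tot = 0; int n = 0;
    int e = e0;
    while (true) {
      used[e] = true;
      seq += g.kmer[e].back();
      tot += g.count[e]; ++n;
      std::string v = g.kmer[e].substr(1);
      if (g.outdeg(v) != 1 || g.indeg(v) != 1) break;
      int nxt = g.out_edges(v)[0];
      if (used[nxt]) break;
      e = nxt;
    }
    seqs.push_back(seq);
    covs.push_back(tot / n);
    lens.push_back(n);
  };

  for (int e : order) {
    if (used[e]) continue;
    std::string u = g.kmer[e].substr(0, g.k - 1);
    if (g.outdeg(u) != 1 || g.indeg(u) != 1) walk(e);
  }
  for (int e : order)  // isolated cycles
    if (!used[e]) walk(e);

  // coverage cutoff, canonical orientation, dedup, deterministic order
  std::vector<std::tuple<std::string, double, int>> out;
  for (size_t i = 0; i < seqs.size(); ++i) {
    if (covs[i] < cov_cutoff) continue;
    std::string s = seqs[i];
    if (canonical) {
      std::string rc = revcomp(s);
      if (rc < s) s = rc;
    }
    out.push_back({s, covs[i], lens[i]});
  }
  std::sort(out.begin(), out.end());
  out.erase(std::unique(out.begin(), out.end(),
                        [](const auto &a, const auto &b) {
                          return std::get<0>(a) == std::get<0>(b);
                        }),
            out.end());
  CharacterVector rs(out.size());
  NumericVector rc(out.size());
  IntegerVector rl(out.size());
  for (size_t i = 0; i < out.size(); ++i) {
    rs[i] = std::get<0>(out[i]);
    rc[i] = std::get<1>(out[i]);
    rl[i] = std::get<2>(out[i]);
  }
  return List::create(_["sequence"] = rs, _["mean_cov"] = rc,
                      _["n_edges"] = rl);
}
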