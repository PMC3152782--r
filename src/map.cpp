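#include <Rcpp.h>
#include <unordered_map>
#include <set>
#include "seq_utils.h"

using namespace Rcpp;

// Exact-seed-and-extend read mapper: gapless, full-length alignment of each
// read against the contig set, allowing up to max_mismatches substitutions.
// Each read is assigned to its unique best position (fewest mismatches);
// reads with several equal-best positions are reported as ambiguous and get
// no hit. Candidate positions are found from exact seed_k-mer matches at a
// tiling of read offsets, on both strands.
// [[Rcpp::export]]
List cpp_map_reads(CharacterVector read_seqs, CharacterVector contig_seqs,
                   int seed_k, int max_mismatches) {
  int nc = contig_seqs.size();
  std::vector<std::string> contigs(nc);
  for (int i = 0; i < nc; ++i) contigs[i] = as<std::string>(contig_seqs[i]);

  typedef std::pair<int, int> Loc;  // contig, pos
  std::unordered_map<std::string, std::vector<Loc>> index;
  for (int c = 0; c < nc; ++c) {
    const std::string &s = contigs[c];
    if ((int)s.size() < seed_k) continue;
    for (size_t p = 0; p + seed_k <= s.size(); ++p)
      index[s.substr(p, seed_k)].push_back({c, (int)p});
  }

  int nr = read_seqs.size();
  std::vector<int> h_read, h_contig, h_pos, h_strand, h_mm;
  int n_ambiguous = 0, n_unmapped = 0;

  for (int r = 0; r < nr; ++r) {
    std::string fwd = as<std::string>(read_seqs[r]);
    int L = (int)fwd.size();
    if (L < seed_k) { ++n_unmapped; continue; }
    std::string rev = revcomp(fwd);
    // candidate (contig, start, strand)
    std::set<std::tuple<int, int, int>> cand;
    std::vector<int> offs;
    for (int o = 0; o + seed_k <= L; o += seed_k) offs.push_back(o);
    if (offs.empty() || offs.back() != L - seed_k) offs.push_back(L - seed_k);
    for (int strand = 0; strand < 2; ++strand) {
      const std::string &q = strand == 0 ? fwd : rev;
      for (int o : offs) {
        auto it = index.find(q.substr(o, seed_k));
        if (it == index.end()) continue;
        for (const Loc &loc : it->second) {
          int start = loc.second - o;
          if (start < 0 || start + L > (int)contigs[loc.first].size()) continue;
          cand.insert({loc.first, start, strand});
        }
      }
    }
    int best_mm = max_mismatches + 1;
    std::vector<std::tuple<int, int, int>> best;
    for (const auto &cd : cand) {
      int c = std::get<0>(cd), start = std::get<1>(cd), strand = std::get<2>(cd);
      const std::string &q = strand == 0 ? fwd : rev;
      const std::string &t = contigs[c];
      int mm = 0;
      for (int i = 0; i < L; ++i) {
        if (q[i] != t[start + i] && ++mm > best_mm) break;
      }
      if (mm < best_mm) { best_mm = mm; best.clear(); best.push_back(cd); }
      else if (mm == best_mm) best.push_back(cd);
    }
    if (best_mm > max_mismatches || best.empty()) { ++n_unmapped; continue; }
    if (best.size() > 1) { ++n_ambiguous; continue; }
    h_read.push_back(r + 1);
    h_contig.push_back(std::get<0>(best[0]) + 1);
    h_pos.push_back(std::get<1>(best[0]));
    h_strand.push_back(std::get<2>(best[0]) == 0 ? 1 : -1);
    h_mm.push_back(best_mm);
  }
  return List::create(_["read"] = wrap(h_read), _["contig"] = wrap(h_contig),
                      _["pos"] = wrap(h_pos), _["strand"] = wrap(h_strand),
                      _["mismatches"] = wrap(h_mm),
                      _["n_ambiguous"] = n_ambiguous,
                      _["n_unmapped"] = n_unmapped);
}

// Per-contig pileup from gapless hits: stranded-read forward/reverse depth,
// total depth over all mapped reads, and A/C/G/T base counts.
// [[Rcpp::export]]
List cpp_pileup(IntegerVector contig_lens, IntegerVector hit_read,
                IntegerVector hit_contig, IntegerVector hit_pos,
                IntegerVector hit_strand, CharacterVector read_seqs,
                LogicalVector read_stranded) {
  int nc = contig_lens.size();
  std::vector<IntegerVector> fwd(nc), rev(nc), tot(nc);
  std::vector<IntegerMatrix> bases(nc);
  for (int c = 0; c < nc; ++c) {
    fwd[c] = IntegerVector(contig_lens[c]);
    rev[c] = IntegerVector(contig_lens[c]);
    tot[c] = IntegerVector(contig_lens[c]);
    bases[c] = IntegerMatrix(contig_lens[c], 4);
  }
  int nh = hit_read.size();
  for (int h = 0; h < nh; ++h) {
    int r = hit_read[h] - 1, c = hit_contig[h] - 1;
    int pos = hit_pos[h], strand = hit_strand[h];
    std::string q = as<std::string>(read_seqs[r]);
    if (strand < 0) q = revcomp(q);
    bool st = read_stranded[r];
    for (size_t i = 0; i < q.size(); ++i) {
      int p = pos + (int)i;
      tot[c][p] += 1;
      if (st) { if (strand > 0) fwd[c][p] += 1; else rev[c][p] += 1; }
      switch (q[i]) {
        case 'A': bases[c](p, 0) += 1; break;
        case 'C': bases[c](p, 1) += 1; break;
        case 'G': bases[c](p, 2) += 1; break;
        case 'T': bases[c](p, 3) += 1; break;
        default: break;
      }
    }
  }
  List out(nc);
  for (int c = 0; c < nc; ++c)
    out[c] = List::create(_["fwd"] = fwd[c], _["rev"] = rev[c],
                          _["total"] = tot[c], _["bases"] = bases[c]);
  return out;
}
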