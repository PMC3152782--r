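#include <Rcpp.h>
#include <unordered_map>
#include "seq_utils.h"

using namespace Rcpp;

// Count k-mers over a read set. Unweighted counting gives each read one
// contribution per position; weighted counting multiplies by read
// multiplicity. K-mers containing non-ACGT characters are skipped.
// [[Rcpp::export]]
List cpp_count_kmers(CharacterVector seqs, IntegerVector mult, int k,
                     bool weighted, bool canonical) {
  std::unordered_map<std::string, double> tab;
  int n = seqs.size();
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    double w = weighted ? (double)mult[i] : 1.0;
    if ((int)s.size() < k) continue;
    for (size_t p = 0; p + k <= s.size(); ++p) {
      if (!clean_kmer(s, p, k)) continue;
      std::string km = s.substr(p, k);
      if (canonical) {
        std::string rc = revcomp(km);
        if (rc < km) km = rc;
      }
      tab[km] += w;
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

// Keep a read iff every N-free k-mer it contains has count >= min_count in
// the supplied table. Reads shorter than k carry no k-mer evidence and are
// kept unless drop_short.
// [[Rcpp::export]]
LogicalVector cpp_filter_reads(CharacterVector seqs, CharacterVector keys,
                               NumericVector counts, int k, double min_count,
                               bool canonical, bool drop_short) {
  std::unordered_map<std::string, double> tab;
  tab.reserve(keys.size() * 2);
  for (int i = 0; i < keys.size(); ++i)
    tab[as<std::string>(keys[i])] = counts[i];
  int n = seqs.size();
  LogicalVector keep(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    if ((int)s.size() < k) { keep[i] = !drop_short; continue; }
    bool ok = true;
    for (size_t p = 0; p + k <= s.size(); ++p) {
      if (!clean_kmer(s, p, k)) continue;
      std::string km = s.substr(p, k);
      if (canonical) {
        std::string rc = revcomp(km);
        if (rc < km) km = rc;
      }
      auto it = tab.find(km);
      double c = (it == tab.end()) ? 0.0 : it->second;
      if (c < min_count) { ok = false; break; }
    }
    keep[i] = ok;
  }
  return keep;
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector seqs) {
  int n = seqs.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) out[i] = revcomp(as<std::string>(seqs[i]));
  return out;
}

// Apply i.i.d. substitution errors at the given per-base rate using R's RNG.
// Returns the mutated sequences and the 1-based error positions per read.
// [[Rcpp::export]]
List cpp_mutate_seqs(CharacterVector seqs, double rate) {
  static const char *alt[4] = {"CGT", "AGT", "ACT", "ACG"};
  int n = seqs.size();
  CharacterVector out(n);
  List pos(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    std::vector<int> ep;
    for (size_t p = 0; p < s.size(); ++p) {
      if (!is_acgt(s[p])) continue;
      if (R::unif_rand() < rate) {
        int b = s[p] == 'A' ? 0 : s[p] == 'C' ? 1 : s[p] == 'G' ? 2 : 3;
        int j = (int)(R::unif_rand() * 3.0);
        if (j > 2) j = 2;
        s[p] = alt[b][j];
        ep.push_back((int)p + 1);
      }
    }
    out[i] = s;
    pos[i] = wrap(ep);
  }
  return List::create(_["sequence"] = out, _["error_pos"] = pos);
}
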