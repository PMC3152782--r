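#ifndef DENOVOTX_SEQ_UTILS_H
#define DENOVOTX_SEQ_UTILS_H

#include <string>
#include <algorithm>

inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
  }
}

inline std::string revcomp(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (auto &c : r) c = comp_base(c);
  return r;
}

inline bool is_acgt(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

// true if s[pos, pos+k) is free of non-ACGT characters
inline bool clean_kmer(const std::string &s, size_t pos, int k) {
  for (int i = 0; i < k; ++i)
    if (!is_acgt(s[pos + i])) return false;
  return true;
}

#endif
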