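#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <cstdint>
#include <algorithm>
using namespace Rcpp;

static inline bool valid_base(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

static inline char complement(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    default:  return 'A';
  }
}

// Count k-mers over the valid (ACGT-only) windows of one or more sequences.
// Windows never span sequence boundaries. Returns sorted distinct k-mers,
// their occurrence counts, and L (the number of counted windows).
// [[Rcpp::export]]
List cpp_count_kmers(CharacterVector seqs, int k, bool canonical) {
  std::unordered_map<std::string, int> counts;
  long long L = 0;
  std::string rc(k, 'N');
  for (R_xlen_t si = 0; si < seqs.size(); ++si) {
    std::string s = as<std::string>(seqs[si]);
    long long n = (long long)s.size();
    if (n < k) continue;
    // run[i] = number of consecutive valid bases ending at i (inclusive)
    long long run = 0;
    for (long long i = 0; i < n; ++i) {
      run = valid_base(s[i]) ? run + 1 : 0;
      if (i >= k - 1 && run >= k) {
        std::string w = s.substr(i - k + 1, k);
        if (canonical) {
          for (int j = 0; j < k; ++j) rc[j] = complement(w[k - 1 - j]);
          if (rc < w) w = rc;
        }
        ++counts[w];
        ++L;
      }
    }
  }
  std::vector<std::string> keys;
  keys.reserve(counts.size());
  for (auto &kv : counts) keys.push_back(kv.first);
  std::sort(keys.begin(), keys.end());
  CharacterVector kmers(keys.size());
  IntegerVector occ(keys.size());
  for (size_t i = 0; i < keys.size(); ++i) {
    kmers[i] = keys[i];
    occ[i] = counts[keys[i]];
  }
  return List::create(_["kmers"] = kmers, _["counts"] = occ,
                      _["L"] = (double)L);
}

// For each k-mer in `kmers` (a distinct set), the number of members of the
// same set at Hamming distance exactly 1, by enumerating all 3k
// single-base substitutions and testing membership.
// [[Rcpp::export]]
IntegerVector cpp_d1_counts(CharacterVector kmers) {
  R_xlen_t m = kmers.size();
  IntegerVector out(m);
  if (m == 0) return out;
  std::unordered_set<std::string> set;
  set.reserve((size_t)(m * 1.5));
  for (R_xlen_t i = 0; i < m; ++i) set.insert(as<std::string>(kmers[i]));
  const char bases[4] = {'A', 'C', 'G', 'T'};
  for (R_xlen_t i = 0; i < m; ++i) {
    std::string tau = as<std::string>(kmers[i]);
    int d1 = 0;
    for (size_t p = 0; p < tau.size(); ++p) {
      char orig = tau[p];
      for (int b = 0; b < 4; ++b) {
        if (bases[b] == orig) continue;
        tau[p] = bases[b];
        if (set.count(tau)) ++d1;
      }
      tau[p] = orig;
    }
    out[i] = d1;
  }
  return out;
}

// Seeded 64-bit hash: FNV-1a over the k-mer bytes followed by a
// splitmix64-style finalizer for avalanche. Retention test uses exact
// integer comparison against floor(theta * 2^64).
static inline uint64_t mix64(uint64_t z) {
  z += 0x9e3779b97f4a7c15ULL;
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  return z ^ (z >> 31);
}

static inline uint64_t hash_kmer(const std::string &s, uint64_t seed) {
  uint64_t h = 14695981039346656037ULL ^ mix64(seed);
  for (char c : s) {
    h ^= (uint64_t)(unsigned char)c;
    h *= 1099511628211ULL;
  }
  return mix64(h);
}

// [[Rcpp::export]]
LogicalVector cpp_hash_keep(CharacterVector kmers, double theta, int seed) {
  R_xlen_t m = kmers.size();
  LogicalVector out(m);
  if (theta >= 1.0) {
    std::fill(out.begin(), out.end(), true);
    return out;
  }
  // threshold = floor(theta * 2^64), computed without overflowing uint64
  long double thr_ld = (long double)theta * 18446744073709551616.0L;
  uint64_t thr = (uint64_t)thr_ld;
  uint64_t useed = (uint64_t)(int64_t)seed;
  for (R_xlen_t i = 0; i < m; ++i) {
    out[i] = hash_kmer(as<std::string>(kmers[i]), useed) < thr;
  }
  return out;
}
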