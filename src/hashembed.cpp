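#include <Rcpp.h>
#include <string>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// 64-bit FNV-1a over the bytes of a feature string, with the seed folded
// into the initial state so different seeds give unrelated hash families.
static inline uint64_t fnv1a(const std::string& s, uint64_t seed) {
  uint64_t h = 14695981039346656037ULL ^ (seed * 1099511628211ULL);
  for (unsigned char c : s) {
    h ^= (uint64_t)c;
    h *= 1099511628211ULL;
  }
  return h;
}

static inline void add_feature(std::vector<double>& v, const std::string& f,
                               uint64_t seed, int d) {
  uint64_t h = fnv1a(f, seed);
  int bucket = (int)(h % (uint64_t)d);
  // use an independent bit for the sign so it is not confounded with the bucket
  double sign = ((h >> 61) & 1ULL) ? 1.0 : -1.0;
  v[bucket] += sign;
}

// Signed feature-hashing embedder for token sequences.
// Features: character n-grams (n = 2..4) of the ", "-joined sequence plus
// adjacent word bigrams; signed counts hashed into d buckets; L2-normalized.
// [[Rcpp::export]]
NumericMatrix hash_embed_cpp(List token_lists, int d, int seed) {
  int n = token_lists.size();
  NumericMatrix out(n, d);
  uint64_t useed = (uint64_t)seed;
  for (int i = 0; i < n; ++i) {
    CharacterVector toks = token_lists[i];
    std::vector<double> v(d, 0.0);
    std::string joined;
    for (int j = 0; j < toks.size(); ++j) {
      if (j > 0) joined += ", ";
      joined += std::string(toks[j]);
    }
    if (joined.empty()) joined = "\x01"; // empty sequence sentinel
    size_t L = joined.size();
    for (int len = 2; len <= 4; ++len) {
      if (L < (size_t)len) continue;
      for (size_t p = 0; p + len <= L; ++p)
        add_feature(v, "c:" + joined.substr(p, len), useed, d);
    }
    for (int j = 0; j + 1 < toks.size(); ++j) {
      std::string bg = "w:" + std::string(toks[j]) + "\x1f" +
                       std::string(toks[j + 1]);
      add_feature(v, bg, useed, d);
    }
    if (toks.size() == 0) add_feature(v, "w:\x01", useed, d);
    double nrm = 0.0;
    for (int k = 0; k < d; ++k) nrm += v[k] * v[k];
    nrm = std::sqrt(nrm);
    if (nrm == 0.0) { v[0] = 1.0; nrm = 1.0; } // unreachable in practice
    for (int k = 0; k < d; ++k) out(i, k) = v[k] / nrm;
  }
  return out;
}
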