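#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <string>

using namespace Rcpp;

// 2-bit base codes: A=0, C=1, G=2, T=3 (lexicographic order preserved),
// so numeric comparison of packed words equals lexicographic comparison
// of equal-length k-mer strings.
static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static const char BASES[4] = {'A', 'C', 'G', 'T'};

// Encode one window; returns false when a non-ACGT character is present.
static bool encode_window(const char *s, int k, uint64_t &fwd, uint64_t &rev) {
  fwd = 0; rev = 0;
  for (int i = 0; i < k; ++i) {
    int b = base_code(s[i]);
    if (b < 0) return false;
    fwd = (fwd << 2) | (uint64_t)b;
    rev |= ((uint64_t)(3 - b)) << (2 * i);
  }
  return true;
}

static inline uint64_t canonical64(uint64_t fwd, uint64_t rev) {
  return fwd < rev ? fwd : rev;
}

static std::string decode_kmer(uint64_t x, int k) {
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) {
    s[i] = BASES[x & 3ULL];
    x >>= 2;
  }
  return s;
}

// splitmix64: fast, well-mixed 64-bit finalizer; seeded variants give the
// d-member hash family for the bloom filter.
static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

struct Bloom {
  std::vector<uint64_t> bits;
  uint64_t m;        // number of bits
  int d;             // number of hash functions
  double n_inserted; // insertion attempts

  Bloom(uint64_t m_, int d_) : bits((m_ + 63) / 64, 0ULL), m(m_), d(d_), n_inserted(0) {}

  inline uint64_t idx(uint64_t key, int i) const {
    return splitmix64(key ^ splitmix64((uint64_t)i)) % m;
  }
  inline bool contains(uint64_t key) const {
    for (int i = 0; i < d; ++i) {
      uint64_t j = idx(key, i);
      if (!(bits[j >> 6] & (1ULL << (j & 63)))) return false;
    }
    return true;
  }
  inline void insert(uint64_t key) {
    for (int i = 0; i < d; ++i) {
      uint64_t j = idx(key, i);
      bits[j >> 6] |= (1ULL << (j & 63));
    }
    n_inserted += 1;
  }
};

// [[Rcpp::export(rng = false)]]
CharacterVector sk_encode_canonical(CharacterVector windows, int k) {
  R_xlen_t n = windows.size();
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (windows[i] == NA_STRING) { out[i] = NA_STRING; continue; }
    const char *s = CHAR(windows[i]);
    if ((int)LENGTH(windows[i]) != k)
      stop("window length must equal k");
    uint64_t fwd, rev;
    if (!encode_window(s, k, fwd, rev)) { out[i] = NA_STRING; continue; }
    out[i] = decode_kmer(canonical64(fwd, rev), k);
  }
  return out;
}

// ---- bloom filter handle exposed to R -------------------------------------

// [[Rcpp::export(rng = false)]]
SEXP sk_bloom_new(double m, int d) {
  if (m < 1 || d < 1) stop("m and d must be >= 1");
  XPtr<Bloom> p(new Bloom((uint64_t)m, d), true);
  return p;
}

// [[Rcpp::export(rng = false)]]
void sk_bloom_insert(SEXP ptr, CharacterVector kmers, int k) {
  XPtr<Bloom> p(ptr);
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    uint64_t fwd, rev;
    if (!encode_window(CHAR(kmers[i]), k, fwd, rev))
      stop("k-mer contains non-ACGT characters");
    p->insert(canonical64(fwd, rev));
  }
}

// [[Rcpp::export(rng = false)]]
LogicalVector sk_bloom_contains(SEXP ptr, CharacterVector kmers, int k) {
  XPtr<Bloom> p(ptr);
  LogicalVector out(kmers.size());
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    uint64_t fwd, rev;
    if (!encode_window(CHAR(kmers[i]), k, fwd, rev))
      stop("k-mer contains non-ACGT characters");
    out[i] = p->contains(canonical64(fwd, rev));
  }
  return out;
}

// [[Rcpp::export(rng = false)]]
List sk_bloom_info(SEXP ptr) {
  XPtr<Bloom> p(ptr);
  double set = 0;
  for (size_t i = 0; i < p->bits.size(); ++i) {
    uint64_t w = p->bits[i];
    while (w) { set += 1; w &= w - 1; }
  }
  return List::create(_["m"] = (double)p->m, _["d"] = p->d,
                      _["n_inserted"] = p->n_inserted, _["bits_set"] = set);
}

// ---- k-mer counting --------------------------------------------------------

// Stream all valid windows of a read, calling f(canonical_kmer).
template <typename F>
static void for_each_canonical(const char *s, int len, int k, F f) {
  uint64_t fwd = 0, rev = 0, mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  int run = 0; // length of current valid-base run
  for (int i = 0; i < len; ++i) {
    int b = base_code(s[i]);
    if (b < 0) { run = 0; fwd = 0; rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)b) & mask;
    rev = (rev >> 2) | (((uint64_t)(3 - b)) << (2 * (k - 1)));
    if (++run >= k) f(canonical64(fwd, rev));
  }
}

// Two-pass exact counting with bloom-based singleton exclusion.
// Pass 1: first sighting goes to the bloom filter only; re-sightings (and
// bloom false positives) open a slot in the candidate table. Pass 2 recounts
// the candidates exactly; candidates whose exact multiplicity is 1 (false
// positive admissions) are dropped.
// [[Rcpp::export(rng = false)]]
List sk_count_kmers(CharacterVector reads, int k, double bloom_m, int bloom_d) {
  if (k < 15 || k > 31) stop("k must be within [15, 31]");
  if (bloom_m < 1 || bloom_d < 1) stop("bloom parameters must be >= 1");
  Bloom bloom((uint64_t)bloom_m, bloom_d);
  std::unordered_map<uint64_t, uint32_t> table;

  double total_bases = 0;
  R_xlen_t n = reads.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    const char *s = CHAR(reads[i]);
    int len = LENGTH(reads[i]);
    total_bases += len;
    for_each_canonical(s, len, k, [&](uint64_t key) {
      if (bloom.contains(key)) {
        table.emplace(key, 0u); // exact count filled in pass 2
      } else {
        bloom.insert(key);
      }
    });
  }

  const uint32_t SAT = 0xFFFFFFFFu;
  for (R_xlen_t i = 0; i < n; ++i) {
    const char *s = CHAR(reads[i]);
    int len = LENGTH(reads[i]);
    for_each_canonical(s, len, k, [&](uint64_t key) {
      auto it = table.find(key);
      if (it != table.end() && it->second < SAT) it->second += 1;
    });
  }

  std::vector<std::pair<uint64_t, uint32_t>> kept;
  kept.reserve(table.size());
  for (auto &kv : table)
    if (kv.second >= 2) kept.push_back(kv);
  std::sort(kept.begin(), kept.end());

  CharacterVector kms(kept.size());
  NumericVector cnts(kept.size());
  for (size_t i = 0; i < kept.size(); ++i) {
    kms[i] = decode_kmer(kept[i].first, k);
    cnts[i] = (double)kept[i].second;
  }
  return List::create(_["kmer"] = kms, _["count"] = cnts,
                      _["total_bases"] = total_bases,
                      _["total_reads"] = (double)n);
}

// Exhaustive (no bloom) counter used for moderate inputs where exactness of
// the candidate set matters more than memory; identical output contract.
// [[Rcpp::export(rng = false)]]
List sk_count_kmers_exact(CharacterVector reads, int k) {
  if (k < 15 || k > 31) stop("k must be within [15, 31]");
  std::unordered_map<uint64_t, uint32_t> table;
  double total_bases = 0;
  R_xlen_t n = reads.size();
  const uint32_t SAT = 0xFFFFFFFFu;
  for (R_xlen_t i = 0; i < n; ++i) {
    const char *s = CHAR(reads[i]);
    int len = LENGTH(reads[i]);
    total_bases += len;
    for_each_canonical(s, len, k, [&](uint64_t key) {
      auto it = table.emplace(key, 0u).first;
      if (it->second < SAT) it->second += 1;
    });
  }
  std::vector<std::pair<uint64_t, uint32_t>> kept;
  for (auto &kv : table)
    if (kv.second >= 2) kept.push_back(kv);
  std::sort(kept.begin(), kept.end());
  CharacterVector kms(kept.size());
  NumericVector cnts(kept.size());
  for (size_t i = 0; i < kept.size(); ++i) {
    kms[i] = decode_kmer(kept[i].first, k);
    cnts[i] = (double)kept[i].second;
  }
  return List::create(_["kmer"] = kms, _["count"] = cnts,
                      _["total_bases"] = total_bases,
                      _["total_reads"] = (double)n);
}

static std::unordered_set<uint64_t> encode_set(CharacterVector kmers, int k) {
  std::unordered_set<uint64_t> set;
  set.reserve(kmers.size() * 2);
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    uint64_t fwd, rev;
    if (!encode_window(CHAR(kmers[i]), k, fwd, rev))
      stop("signature k-mer contains non-ACGT characters");
    set.insert(canonical64(fwd, rev));
  }
  return set;
}

// Per-read counts of valid windows (V) and signature-member windows (D).
// [[Rcpp::export(rng = false)]]
List sk_signature_hits(CharacterVector reads, CharacterVector sig, int k) {
  std::unordered_set<uint64_t> set = encode_set(sig, k);
  R_xlen_t n = reads.size();
  IntegerVector valid(n), hits(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const char *s = CHAR(reads[i]);
    int len = LENGTH(reads[i]);
    int V = 0, D = 0;
    for_each_canonical(s, len, k, [&](uint64_t key) {
      ++V;
      if (set.count(key)) ++D;
    });
    valid[i] = V; hits[i] = D;
  }
  return List::create(_["valid"] = valid, _["hits"] = hits);
}

// Window-level membership along one sequence: for each window start, 1 if the
// canonical k-mer is in the set, 0 if absent, NA for invalid windows.
// [[Rcpp::export(rng = false)]]
IntegerVector sk_window_membership(std::string seq, CharacterVector sig, int k) {
  std::unordered_set<uint64_t> set = encode_set(sig, k);
  int len = (int)seq.size();
  int nwin = len - k + 1;
  if (nwin < 1) return IntegerVector(0);
  IntegerVector out(nwin, NA_INTEGER);
  const char *s = seq.c_str();
  uint64_t fwd = 0, rev = 0, mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  int run = 0;
  for (int i = 0; i < len; ++i) {
    int b = base_code(s[i]);
    if (b < 0) { run = 0; fwd = 0; rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)b) & mask;
    rev = (rev >> 2) | (((uint64_t)(3 - b)) << (2 * (k - 1)));
    if (++run >= k)
      out[i - k + 1] = set.count(canonical64(fwd, rev)) ? 1 : 0;
  }
  return out;
}

// All distinct canonical k-mers of a set of sequences (singletons included);
// used to anchor contigs onto a reference.
// [[Rcpp::export(rng = false)]]
CharacterVector sk_distinct_kmers(CharacterVector seqs, int k) {
  std::unordered_set<uint64_t> set;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    const char *s = CHAR(seqs[i]);
    int len = LENGTH(seqs[i]);
    for_each_canonical(s, len, k, [&](uint64_t key) { set.insert(key); });
  }
  std::vector<uint64_t> keys(set.begin(), set.end());
  std::sort(keys.begin(), keys.end());
  CharacterVector out(keys.size());
  for (size_t i = 0; i < keys.size(); ++i) out[i] = decode_kmer(keys[i], k);
  return out;
}
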