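// Core string kernels: prefix-subsampled k-mer counting (sort-based),
// grouped multi-sample counting, read labelling by sex-specific k-mer
// content, read simulation, and seed-and-extend placement.
// All RNG goes through R's generator so set.seed() governs determinism.
#include <Rcpp.h>
#include <climits>
#include <algorithm>
#ifdef __GLIBC__
#include <malloc.h>
#endif
#include <unordered_map>
#include <cstring>
#include <cstdio>
#include <string>
#include <vector>

using namespace Rcpp;

// The heavy kernels allocate and free multi-hundred-MB scratch buffers per
// call; with glibc's default mmap threshold every cycle pays munmap +
// page-zeroing in the kernel. Keeping large blocks on the main arena lets
// the allocator recycle them.
static void keep_large_allocs() {
#ifdef __GLIBC__
  static bool done = false;
  if (!done) {
    mallopt(M_MMAP_THRESHOLD, 512 * 1024 * 1024);
    mallopt(M_TRIM_THRESHOLD, 512 * 1024 * 1024);
    done = true;
  }
#endif
}

// ---- 2-bit packing -------------------------------------------------------

// A <= 64-mer packed into two 64-bit words (2 bits/base, A=0 C=1 G=2 T=3).
// Packed order equals lexicographic order over ACGT strings of fixed k.
struct Key {
  uint64_t hi, lo;
  bool operator==(const Key& o) const { return hi == o.hi && lo == o.lo; }
  bool operator<(const Key& o) const {
    return hi != o.hi ? hi < o.hi : lo < o.lo;
  }
};

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9e3779b97f4a7c15ULL;
  x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
  x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
  return x ^ (x >> 31);
}

struct KeyHash {
  size_t operator()(const Key& k) const {
    return (size_t)(splitmix64(k.hi) ^ splitmix64(k.lo + 0x9e3779b97f4a7c15ULL));
  }
};

static inline int base2bits(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static const char BITS2BASE[4] = {'A', 'C', 'G', 'T'};

// pack s[0..k) into key; false if any non-ACGT letter
static inline bool pack_kmer(const char* s, int k, Key& key) {
  uint64_t hi = 0, lo = 0;
  int i = 0;
  int nhi = (k > 32) ? (k - 32) : 0;
  for (; i < nhi; ++i) {
    int b = base2bits(s[i]);
    if (b < 0) return false;
    hi = (hi << 2) | (uint64_t)b;
  }
  for (; i < k; ++i) {
    int b = base2bits(s[i]);
    if (b < 0) return false;
    lo = (lo << 2) | (uint64_t)b;
  }
  key.hi = hi; key.lo = lo;
  return true;
}

static inline void unpack_kmer(const Key& key, int k, char* out) {
  int nhi = (k > 32) ? (k - 32) : 0;
  uint64_t hi = key.hi, lo = key.lo;
  for (int i = k - 1; i >= nhi; --i) { out[i] = BITS2BASE[lo & 3ULL]; lo >>= 2; }
  for (int i = nhi - 1; i >= 0; --i) { out[i] = BITS2BASE[hi & 3ULL]; hi >>= 2; }
}

static inline char comp_base(char c) {
  switch (c) {
    case 'A': case 'a': return 'T';
    case 'C': case 'c': return 'G';
    case 'G': case 'g': return 'C';
    case 'T': case 't': return 'A';
    default: return 'N';
  }
}

static void revcomp_into(const char* s, int n, std::string& out) {
  out.resize(n);
  for (int i = 0; i < n; ++i) out[i] = comp_base(s[n - 1 - i]);
}

static inline bool has_prefix(const char* s, const char* pre, int plen) {
  for (int i = 0; i < plen; ++i) {
    char c = s[i];
    if (c >= 'a' && c <= 'z') c -= 32;
    if (c != pre[i]) return false;
  }
  return true;
}

// ---- k-mer collection (both orientations) --------------------------------

static void collect_seq(const char* s, int n, int k, const char* pre,
                        int plen, std::vector<Key>& keys) {
  Key key;
  for (int i = 0; i + k <= n; ++i) {
    if (plen > 0 && !has_prefix(s + i, pre, plen)) continue;
    if (!pack_kmer(s + i, k, key)) continue;  // window contains N
    keys.push_back(key);
  }
}

static void collect_reads(CharacterVector reads, int k,
                          const std::string& prefix, std::vector<Key>& keys) {
  std::string rc;
  const char* pre = prefix.c_str();
  int plen = (int)prefix.size();
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    const char* s = CHAR(STRING_ELT(reads, r));
    int n = (int)std::strlen(s);
    collect_seq(s, n, k, pre, plen, keys);
    revcomp_into(s, n, rc);
    collect_seq(rc.c_str(), n, k, pre, plen, keys);
  }
}

// sort + run-length encode a key vector in place; returns unique keys and
// counts through the output arguments
static void sort_count(std::vector<Key>& keys, std::vector<Key>& uk,
                       std::vector<int>& uc) {
  std::sort(keys.begin(), keys.end());
  uk.clear(); uc.clear();
  size_t i = 0, n = keys.size();
  while (i < n) {
    size_t j = i + 1;
    while (j < n && keys[j] == keys[i]) ++j;
    if (j - i > (size_t)INT_MAX) stop("k-mer count overflow (int32)");
    uk.push_back(keys[i]);
    uc.push_back((int)(j - i));
    i = j;
  }
}

static CharacterVector decode_keys(const std::vector<Key>& uk, int k) {
  CharacterVector out(uk.size());
  std::vector<char> buf(k, 'A');
  for (size_t i = 0; i < uk.size(); ++i) {
    unpack_kmer(uk[i], k, buf.data());
    out[i] = Rf_mkCharLen(buf.data(), k);
  }
  return out;
}

// [[Rcpp::export]]
List cpp_count_kmers(CharacterVector reads, int k, std::string prefix) {
  keep_large_allocs();
  if (k <= 0 || k > 64) stop("k must be in 1..64");
  std::vector<Key> keys;
  keys.reserve(1 << 16);
  collect_reads(reads, k, prefix, keys);
  std::vector<Key> uk; std::vector<int> uc;
  sort_count(keys, uk, uc);
  return List::create(_["kmer"] = decode_keys(uk, k),
                      _["count"] = IntegerVector(uc.begin(), uc.end()));
}

static inline double bitcast_u64(uint64_t x) {
  double d;
  std::memcpy(&d, &x, 8);
  return d;
}

static inline uint64_t bitcast_dbl(double d) {
  uint64_t x;
  std::memcpy(&x, &d, 8);
  return x;
}

// decode packed keys (two bit-cast double columns) into k-mer strings
// [[Rcpp::export]]
CharacterVector cpp_decode_packed(NumericVector hi, NumericVector lo,
                                  int k) {
  R_xlen_t n = hi.size();
  CharacterVector out(n);
  std::vector<char> buf(k, 'A');
  Key key;
  for (R_xlen_t i = 0; i < n; ++i) {
    key.hi = bitcast_dbl(hi[i]);
    key.lo = bitcast_dbl(lo[i]);
    unpack_kmer(key, k, buf.data());
    out[i] = Rf_mkCharLen(buf.data(), k);
  }
  return out;
}

// Multi-sample fused path: per-sample sort-based counting followed by a
// merge over the sorted per-sample tables. Returns the union of k-mers
// (sorted) and a k-mers x samples count matrix. With decode = false the
// union is returned packed (bit-cast doubles, columns hi/lo) instead of
// as strings, which avoids interning millions of CHARSXPs.
// [[Rcpp::export]]
List cpp_grouped_counts(List read_sets, int k, std::string prefix,
                        bool decode) {
  keep_large_allocs();
  if (k <= 0 || k > 64) stop("k must be in 1..64");
  int ns = read_sets.size();
  std::vector<std::vector<Key> > uks(ns);
  std::vector<std::vector<int> > ucs(ns);
  {
    std::vector<Key> keys;  // reused buffer across samples
    for (int s = 0; s < ns; ++s) {
      CharacterVector reads(read_sets[s]);
      keys.clear();
      // expected yield: both strands, 4^-prefix subsample of all k-windows
      double est = 0;
      if (reads.size() > 0) {
        int n0 = (int)std::strlen(CHAR(STRING_ELT(reads, 0)));
        est = 2.0 * reads.size() * std::max(n0 - k + 1, 1) /
              std::pow(4.0, (double)prefix.size());
      }
      if (est > 0 && est < 4e9) keys.reserve((size_t)(est * 1.15));
      collect_reads(reads, k, prefix, keys);
      sort_count(keys, uks[s], ucs[s]);
    }
  }
  // union of sorted key lists
  std::vector<Key> uni;
  {
    size_t tot = 0;
    for (int s = 0; s < ns; ++s) tot += uks[s].size();
    uni.reserve(tot);
    for (int s = 0; s < ns; ++s)
      uni.insert(uni.end(), uks[s].begin(), uks[s].end());
    std::sort(uni.begin(), uni.end());
    uni.erase(std::unique(uni.begin(), uni.end()), uni.end());
  }
  R_xlen_t m = (R_xlen_t)uni.size();
  IntegerMatrix counts(m, ns);
  for (int s = 0; s < ns; ++s) {
    const std::vector<Key>& uk = uks[s];
    const std::vector<int>& uc = ucs[s];
    size_t p = 0;
    for (size_t i = 0; i < uk.size(); ++i) {
      while (p < uni.size() && uni[p] < uk[i]) ++p;
      counts((R_xlen_t)p, s) = uc[i];
    }
    uks[s].clear(); uks[s].shrink_to_fit();
  }
  if (decode)
    return List::create(_["kmer"] = decode_keys(uni, k),
                        _["counts"] = counts);
  NumericVector hi(m), lo(m);
  for (R_xlen_t i = 0; i < m; ++i) {
    hi[i] = bitcast_u64(uni[i].hi);
    lo[i] = bitcast_u64(uni[i].lo);
  }
  return List::create(_["hi"] = hi, _["lo"] = lo, _["counts"] = counts);
}

// ---- read labelling ------------------------------------------------------

// fused MSK/FSK catalog: packed key -> flags (1 = MSK, 2 = FSK)
typedef std::unordered_map<Key, unsigned char, KeyHash> FlagMap;

static void add_set(FlagMap& map, CharacterVector kmers, int k,
                    unsigned char flag) {
  Key key;
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    const char* s = CHAR(STRING_ELT(kmers, i));
    if ((int)std::strlen(s) != k) stop("catalog k-mer length != k");
    if (!pack_kmer(s, k, key)) stop("catalog k-mer contains non-ACGT letters");
    map[key] |= flag;
  }
}

static void hits_seq(const char* s, int n, int k, const char* pre, int plen,
                     const FlagMap& map, int& m, int& f) {
  Key key;
  for (int i = 0; i + k <= n; ++i) {
    if (plen > 0 && !has_prefix(s + i, pre, plen)) continue;
    if (!pack_kmer(s + i, k, key)) continue;
    FlagMap::const_iterator it = map.find(key);
    if (it == map.end()) continue;
    if (it->second & 1) ++m;
    if (it->second & 2) ++f;
  }
}

// Returns per read: 1 = male-specific, 2 = female-specific, 3 = ambiguous,
// 0 = unlabeled.
// [[Rcpp::export]]
IntegerVector cpp_label_reads(CharacterVector reads, CharacterVector msk,
                              CharacterVector fsk, int k, std::string prefix,
                              int min_hits) {
  FlagMap map;
  map.reserve((msk.size() + fsk.size()) * 2 + 16);
  add_set(map, msk, k, 1);
  add_set(map, fsk, k, 2);
  const char* pre = prefix.c_str();
  int plen = (int)prefix.size();
  IntegerVector out(reads.size());
  std::string rc;
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    const char* s = CHAR(STRING_ELT(reads, r));
    int n = (int)std::strlen(s);
    int m = 0, f = 0;
    if (!map.empty()) {
      hits_seq(s, n, k, pre, plen, map, m, f);
      revcomp_into(s, n, rc);
      hits_seq(rc.c_str(), n, k, pre, plen, map, m, f);
    }
    int lab;
    if (m >= 1 && f >= 1) lab = 3;
    else if (m >= min_hits && m >= 1) lab = 1;
    else if (f >= min_hits && f >= 1) lab = 2;
    else lab = 0;
    out[r] = lab;
  }
  return out;
}

// ---- read simulation -----------------------------------------------------

// Draw single-end reads from one haplotype sequence. Positions uniform,
// strand uniform, substitution errors Binomial(read_length, error_rate)
// with uniformly drawn offsets (collisions negligible at the rates used).
// Read names are "<name_prefix>|<pos>|<strand>|<i>" (pos 0-based on the
// source haplotype) — the truth channel for placement tests.
// [[Rcpp::export]]
List cpp_sim_reads(std::string seq, int n_reads, int read_length,
                   double error_rate, std::string name_prefix,
                   bool make_names) {
  int L = (int)seq.size();
  if (read_length > L) stop("read_length exceeds sequence length");
  CharacterVector out(n_reads), names(make_names ? n_reads : 0);
  IntegerVector pos(n_reads);
  LogicalVector fwdv(n_reads);
  std::string buf, rc;
  char nbuf[256];
  for (int i = 0; i < n_reads; ++i) {
    int p = (int)(unif_rand() * (L - read_length + 1));
    if (p > L - read_length) p = L - read_length;
    bool fwd = unif_rand() < 0.5;
    buf.assign(seq, p, read_length);
    if (!fwd) { revcomp_into(buf.c_str(), read_length, rc); buf = rc; }
    if (error_rate > 0) {
      int nerr = (int)R::rbinom((double)read_length, error_rate);
      for (int e = 0; e < nerr; ++e) {
        int off = (int)(unif_rand() * read_length);
        if (off >= read_length) off = read_length - 1;
        char old = buf[off];
        int b = base2bits(old);
        if (b < 0) continue;
        int nb = (b + 1 + (int)(unif_rand() * 3)) & 3;
        buf[off] = BITS2BASE[nb];
      }
    }
    out[i] = Rf_mkCharLen(buf.c_str(), read_length);
    if (make_names) {
      int nn = std::snprintf(nbuf, sizeof(nbuf), "%s|%d|%c|%d",
                             name_prefix.c_str(), p, fwd ? '+' : '-', i + 1);
      names[i] = Rf_mkCharLen(nbuf, nn);
    }
    pos[i] = p;
    fwdv[i] = fwd;
  }
  return List::create(_["seq"] = out, _["name"] = names, _["pos"] = pos,
                      _["fwd"] = fwdv);
}

// ---- seed-and-extend placement ------------------------------------------

struct IndexEntry {
  Key key;
  long long pos;  // global 0-based position; -1 marks an ambiguous key
  bool operator<(const IndexEntry& o) const { return key < o.key; }
};

// Index every forward-strand k-mer of the reference in a sorted array.
// A read is placed when exactly one seed hit (over both orientations)
// exists and the full read matches with <= max_mismatch substitutions.
// [[Rcpp::export]]
List cpp_place_reads(CharacterVector ref, CharacterVector reads, int k,
                     int max_mismatch) {
  keep_large_allocs();
  if (k <= 0 || k > 64) stop("k must be in 1..64");
  int nchrom = (int)ref.size();
  std::vector<const char*> seqs(nchrom);
  std::vector<long long> offset(nchrom + 1, 0);
  for (int c = 0; c < nchrom; ++c) {
    seqs[c] = CHAR(STRING_ELT(ref, c));
    offset[c + 1] = offset[c] + (long long)std::strlen(seqs[c]);
  }
  long long total = offset[nchrom];
  std::vector<IndexEntry> index;
  index.reserve((size_t)total);
  for (int c = 0; c < nchrom; ++c) {
    const char* s = seqs[c];
    long long n = offset[c + 1] - offset[c];
    IndexEntry e;
    for (long long i = 0; i + k <= n; ++i) {
      if (!pack_kmer(s + i, k, e.key)) continue;
      e.pos = offset[c] + i;
      index.push_back(e);
    }
  }
  std::sort(index.begin(), index.end());
  // mark repeated keys ambiguous (pos -1 on the first entry of each run)
  {
    size_t i = 0, n = index.size();
    while (i < n) {
      size_t j = i + 1;
      while (j < n && index[j].key == index[i].key) ++j;
      if (j - i > 1) index[i].pos = -1;
      i = j;
    }
  }
  R_xlen_t nr = reads.size();
  IntegerVector chrom(nr, NA_INTEGER);
  IntegerVector start(nr, NA_INTEGER);
  CharacterVector strand(nr);
  std::string rc;
  IndexEntry probe;
  for (R_xlen_t r = 0; r < nr; ++r) {
    const char* s = CHAR(STRING_ELT(reads, r));
    int n = (int)std::strlen(s);
    strand[r] = NA_STRING;
    if (n < k) continue;
    revcomp_into(s, n, rc);
    long long hit_pos = -1;
    int hit_off = 0; bool hit_fwd = true; int nhits = 0;
    for (int ori = 0; ori < 2 && nhits < 2; ++ori) {
      const char* q = ori == 0 ? s : rc.c_str();
      int off = -1;
      for (int i = 0; i + k <= n; ++i)
        if (pack_kmer(q + i, k, probe.key)) { off = i; break; }
      if (off < 0) continue;
      std::vector<IndexEntry>::const_iterator it =
          std::lower_bound(index.begin(), index.end(), probe);
      if (it == index.end() || !(it->key == probe.key)) continue;
      if (it->pos < 0) { nhits = 2; break; }  // repeated k-mer in reference
      ++nhits;
      hit_pos = it->pos; hit_off = off; hit_fwd = (ori == 0);
    }
    if (nhits != 1 || hit_pos < 0) continue;
    int c = 0;
    while (c < nchrom && offset[c + 1] <= hit_pos) ++c;
    long long st = hit_pos - hit_off;           // global read start
    if (st < offset[c] || st + n > offset[c + 1]) continue;
    const char* q = hit_fwd ? s : rc.c_str();
    const char* t = seqs[c] + (st - offset[c]);
    int mm = 0;
    for (int i = 0; i < n && mm <= max_mismatch; ++i) {
      char a = q[i], b = t[i];
      if (a >= 'a') a -= 32;
      if (b >= 'a') b -= 32;
      if (a != b) ++mm;
    }
    if (mm > max_mismatch) continue;
    chrom[r] = c + 1;
    start[r] = (int)(st - offset[c]);
    strand[r] = hit_fwd ? "+" : "-";
  }
  return List::create(_["chrom"] = chrom, _["start"] = start,
                      _["strand"] = strand);
}

// ---- reverse complement (vectorized, used by R-side helpers) -------------

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector x) {
  CharacterVector out(x.size());
  std::string rc;
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    const char* s = CHAR(STRING_ELT(x, i));
    revcomp_into(s, (int)std::strlen(s), rc);
    out[i] = Rf_mkCharLen(rc.c_str(), (int)rc.size());
  }
  return out;
}
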