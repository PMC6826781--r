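// Canonical k-mer counting over FASTA/FASTQ streams or in-memory sequences.
// Counts live in a flat open-addressing hash table (2-bit packed k-mers,
// linear probing) behind an external pointer, so genome-scale spectra can
// be queried (histogram, abundant k-mer extraction) without round-tripping
// millions of k-mer strings through R.
#include <Rcpp.h>
#include <cstdint>
#include <fstream>
#include <string>
#include <vector>
#include <algorithm>

using namespace Rcpp;

static inline uint64_t mix64(uint64_t x) {  // splitmix64 finalizer
  x += 0x9e3779b97f4a7c15ULL;
  x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
  x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
  return x ^ (x >> 31);
}

struct KmerStore {
  int k;
  double total_instances;
  // open addressing, linear probing; keys store canon + 1 (0 = empty slot)
  std::vector<uint64_t> keys;
  std::vector<uint32_t> vals;
  size_t n_used;
  uint64_t mask;

  void init(size_t pow2) {
    keys.assign((size_t)1 << pow2, 0);
    vals.assign((size_t)1 << pow2, 0);
    n_used = 0;
    mask = ((uint64_t)1 << pow2) - 1;
  }
  void grow() {
    std::vector<uint64_t> ok;
    std::vector<uint32_t> ov;
    ok.swap(keys); ov.swap(vals);
    uint64_t omask = mask;
    keys.assign((omask + 1) << 1, 0);
    vals.assign((omask + 1) << 1, 0);
    mask = ((omask + 1) << 1) - 1;
    for (size_t i = 0; i <= omask; ++i) {
      if (!ok[i]) continue;
      uint64_t j = mix64(ok[i]) & mask;
      while (keys[j]) j = (j + 1) & mask;
      keys[j] = ok[i];
      vals[j] = ov[i];
    }
  }
  inline void add(uint64_t canon, uint32_t c) {
    if (n_used * 10 >= (mask + 1) * 7) grow();
    uint64_t key = canon + 1;
    uint64_t j = mix64(key) & mask;
    while (true) {
      if (keys[j] == key) { vals[j] += c; return; }
      if (!keys[j]) { keys[j] = key; vals[j] = c; ++n_used; return; }
      j = (j + 1) & mask;
    }
  }
};

static inline int base2bits(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
  }
  return -1;
}

static const char BITS2BASE[4] = {'A', 'C', 'G', 'T'};

static std::string decode_kmer(uint64_t x, int k) {
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) {
    s[i] = BITS2BASE[x & 3ULL];
    x >>= 2;
  }
  return s;
}

// Roll one sequence into the table: canonical = min(forward, revcomp).
static void count_sequence(const char* seq, size_t n, int k, KmerStore& st) {
  const uint64_t kmask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  const int shift_rc = 2 * (k - 1);
  uint64_t fwd = 0, rev = 0;
  int valid = 0;
  for (size_t i = 0; i < n; ++i) {
    int b = base2bits(seq[i]);
    if (b < 0) { valid = 0; fwd = 0; rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)b) & kmask;
    rev = (rev >> 2) | ((uint64_t)(3 - b) << shift_rc);
    if (++valid >= k) {
      st.add(fwd < rev ? fwd : rev, 1);
      st.total_instances += 1.0;
    }
  }
}

static void check_k(int k) {
  if (k < 3 || k > 31 || k % 2 == 0)
    stop("k must be odd and between 3 and 31 (got %d)", k);
}

// [[Rcpp::export]]
SEXP cpp_spectrum_new(int k) {
  check_k(k);
  KmerStore* st = new KmerStore();
  st->k = k;
  st->total_instances = 0.0;
  st->init(16);  // 64k slots; grows by doubling at 70% load
  XPtr<KmerStore> ptr(st, true);
  return ptr;
}

// [[Rcpp::export]]
void cpp_spectrum_add_seqs(SEXP ptr_, CharacterVector seqs) {
  XPtr<KmerStore> ptr(ptr_);
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    count_sequence(s, std::strlen(s), ptr->k, *ptr);
  }
}

// Stream one FASTQ or FASTA file (auto-detected from the first byte).
// [[Rcpp::export]]
void cpp_spectrum_add_file(SEXP ptr_, std::string path) {
  XPtr<KmerStore> ptr(ptr_);
  std::ifstream in(path.c_str());
  if (!in) stop("cannot open reads file '%s'", path.c_str());
  int c = in.peek();
  if (c == EOF) return;
  std::string line;
  if (c == '>') {  // FASTA: accumulate per record
    std::string seq;
    while (std::getline(in, line)) {
      if (!line.empty() && line[0] == '>') {
        if (!seq.empty()) count_sequence(seq.c_str(), seq.size(), ptr->k, *ptr);
        seq.clear();
      } else {
        seq += line;
      }
    }
    if (!seq.empty()) count_sequence(seq.c_str(), seq.size(), ptr->k, *ptr);
  } else if (c == '@') {  // FASTQ: 4-line records, validated
    long rec = 0;
    std::string hdr, seq, sep, qual;
    while (std::getline(in, hdr)) {
      if (hdr.empty()) continue;
      ++rec;
      if (hdr[0] != '@')
        stop("malformed FASTQ record %ld in '%s': header does not start with '@'", rec, path.c_str());
      if (!std::getline(in, seq) || !std::getline(in, sep) || !std::getline(in, qual))
        stop("malformed FASTQ record %ld in '%s': truncated record", rec, path.c_str());
      if (sep.empty() || sep[0] != '+')
        stop("malformed FASTQ record %ld in '%s': missing '+' separator", rec, path.c_str());
      if (qual.size() != seq.size())
        stop("malformed FASTQ record %ld in '%s': quality length differs from sequence length", rec, path.c_str());
      count_sequence(seq.c_str(), seq.size(), ptr->k, *ptr);
    }
  } else {
    stop("'%s' does not look like FASTA or FASTQ (first byte '%c')", path.c_str(), (char)c);
  }
}

// Load explicit (kmer, count) pairs, e.g. from a persisted TSV.
// [[Rcpp::export]]
void cpp_spectrum_add_counts(SEXP ptr_, CharacterVector kmers, NumericVector counts) {
  XPtr<KmerStore> ptr(ptr_);
  const int k = ptr->k;
  const int shift_rc = 2 * (k - 1);
  const uint64_t kmask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    const char* s = CHAR(STRING_ELT(kmers, i));
    if ((int)std::strlen(s) != k) stop("k-mer %d has length != k", (int)i + 1);
    uint64_t fwd = 0, rev = 0;
    for (int j = 0; j < k; ++j) {
      int b = base2bits(s[j]);
      if (b < 0) stop("k-mer %d contains a non-ACGT base", (int)i + 1);
      fwd = ((fwd << 2) | (uint64_t)b) & kmask;
      rev = (rev >> 2) | ((uint64_t)(3 - b) << shift_rc);
    }
    double cnt = counts[i];
    if (cnt < 0) stop("negative k-mer count");
    if (cnt > 0) {
      ptr->add(fwd < rev ? fwd : rev, (uint32_t)cnt);
      ptr->total_instances += cnt;
    }
  }
}

// Histogram: count value -> number of distinct canonical k-mers.
// [[Rcpp::export]]
List cpp_spectrum_histogram(SEXP ptr_) {
  XPtr<KmerStore> ptr(ptr_);
  std::vector<double> hist;  // indexed by count for small counts
  const uint32_t SMALL = 1 << 16;
  hist.assign(SMALL, 0.0);
  std::vector<std::pair<uint32_t, double> > big;
  for (size_t i = 0; i <= ptr->mask; ++i) {
    if (!ptr->keys[i]) continue;
    uint32_t c = ptr->vals[i];
    if (c < SMALL) hist[c] += 1.0;
    else {
      bool found = false;
      for (size_t j = 0; j < big.size(); ++j)
        if (big[j].first == c) { big[j].second += 1.0; found = true; break; }
      if (!found) big.push_back(std::make_pair(c, 1.0));
    }
  }
  std::vector<std::pair<uint32_t, double> > out;
  for (uint32_t c = 1; c < SMALL; ++c)
    if (hist[c] > 0) out.push_back(std::make_pair(c, hist[c]));
  out.insert(out.end(), big.begin(), big.end());
  std::sort(out.begin(), out.end());
  NumericVector count(out.size()), nk(out.size());
  for (size_t i = 0; i < out.size(); ++i) {
    count[i] = out[i].first;
    nk[i] = out[i].second;
  }
  return List::create(_["count"] = count, _["n_kmers"] = nk,
                      _["n_distinct"] = (double)ptr->n_used,
                      _["total_instances"] = ptr->total_instances);
}

// All k-mers with count >= threshold, as strings (call only when the
// qualifying set is expected to be modest).
// [[Rcpp::export]]
List cpp_spectrum_extract(SEXP ptr_, double threshold) {
  XPtr<KmerStore> ptr(ptr_);
  std::vector<std::pair<uint64_t, uint32_t> > sel;
  for (size_t i = 0; i <= ptr->mask; ++i)
    if (ptr->keys[i] && ptr->vals[i] >= threshold)
      sel.push_back(std::make_pair(ptr->keys[i] - 1, ptr->vals[i]));
  std::sort(sel.begin(), sel.end());
  CharacterVector km(sel.size());
  NumericVector ct(sel.size());
  for (size_t i = 0; i < sel.size(); ++i) {
    km[i] = decode_kmer(sel[i].first, ptr->k);
    ct[i] = sel[i].second;
  }
  return List::create(_["kmer"] = km, _["count"] = ct);
}

// [[Rcpp::export]]
int cpp_spectrum_k(SEXP ptr_) {
  XPtr<KmerStore> ptr(ptr_);
  return ptr->k;
}
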