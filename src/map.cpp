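// Best-hit read placement against a small reference set (repeat library or
// genomic scaffolds): exact-word seeding at stepped offsets on both strands,
// diagonal voting, ungapped rescoring of the top diagonals, per-base depth
// accumulation. References are assumed to be pre-sorted by id so that ties
// resolve toward the lexicographically smallest sequence id.
#include <Rcpp.h>
#include <cstdint>
#include <fstream>
#include <string>
#include <unordered_map>
#include <vector>
#include <algorithm>

using namespace Rcpp;

static inline int b2i(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
  }
  return -1;
}

struct SeedIndex {
  int seed_len;
  int max_occ;
  std::vector<std::string> seqs;   // reference sequences (id order = input order)
  std::unordered_map<uint64_t, std::vector<uint64_t> > pos;  // word -> packed (ref << 32 | pos)
};

// [[Rcpp::export]]
SEXP cpp_build_index(CharacterVector refs, int seed_len, int max_occ) {
  if (seed_len < 8 || seed_len > 31) stop("seed_len must be in [8, 31]");
  SeedIndex* ix = new SeedIndex();
  ix->seed_len = seed_len;
  ix->max_occ = max_occ;
  const uint64_t mask = (seed_len < 32) ? ((1ULL << (2 * seed_len)) - 1) : ~0ULL;
  for (R_xlen_t r = 0; r < refs.size(); ++r) {
    std::string s = as<std::string>(refs[r]);
    ix->seqs.push_back(s);
    uint64_t w = 0; int valid = 0;
    for (size_t j = 0; j < s.size(); ++j) {
      int b = b2i(s[j]);
      if (b < 0) { valid = 0; w = 0; continue; }
      w = ((w << 2) | (uint64_t)b) & mask;
      if (++valid >= seed_len) {
        std::vector<uint64_t>& v = ix->pos[w];
        if (max_occ <= 0 || (int)v.size() < max_occ)
          v.push_back(((uint64_t)r << 32) | (uint64_t)(j - seed_len + 1));
      }
    }
  }
  XPtr<SeedIndex> ptr(ix, true);
  return ptr;
}

static void revcomp_inplace(std::string& s) {
  std::reverse(s.begin(), s.end());
  for (size_t i = 0; i < s.size(); ++i) {
    switch (s[i]) {
      case 'A': case 'a': s[i] = 'T'; break;
      case 'C': case 'c': s[i] = 'G'; break;
      case 'G': case 'g': s[i] = 'C'; break;
      case 'T': case 't': s[i] = 'A'; break;
      default: s[i] = 'N';
    }
  }
}

struct Placement {
  bool ok;
  int ref, start, end, matches, overlap;
  int strand;  // 0 = forward, 1 = reverse
};

// Evaluate a candidate diagonal: the best-scoring ungapped run of the read
// against the reference at this offset (match +1 / mismatch -2, maximal
// scoring segment), so reads spanning an indel or an array boundary are
// soft-clipped to their well-aligned part.
static void eval_diag(const std::string& read, const std::string& ref,
                      int ref_id, long diag, int strand, Placement& best) {
  const int rl = (int)read.size(), fl = (int)ref.size();
  // read position i aligns to ref position diag + i
  long lo = std::max(0L, -diag);                 // first read index inside ref
  long hi = std::min((long)rl, (long)fl - diag); // one-past-last read index
  if (hi - lo < 20) return;
  long run_start = lo, cur_start = lo;
  long best_s = lo, best_e = lo;
  int cur = 0, bestsc = -1;
  int cur_m = 0, best_m = 0;
  for (long i = lo; i < hi; ++i) {
    bool eq = read[i] == ref[diag + i];
    int d = eq ? 1 : -2;
    if (cur + d < d) { cur = d; cur_start = i; cur_m = eq ? 1 : 0; }
    else { cur += d; cur_m += eq ? 1 : 0; }
    if (cur > bestsc) { bestsc = cur; best_s = cur_start; best_e = i + 1; best_m = cur_m; }
  }
  // re-count matches within the chosen segment (cur_m tracks the running
  // segment, which may extend past the recorded optimum)
  int matches = 0;
  for (long i = best_s; i < best_e; ++i)
    if (read[i] == ref[diag + i]) ++matches;
  lo = best_s; hi = best_e;
  if (hi - lo < 20) return;
  int overlap = (int)(hi - lo);
  bool better = false;
  if (!best.ok) better = true;
  else if (matches > best.matches) better = true;
  else if (matches == best.matches) {
    // ties: lexicographically smallest ref id (== smallest index after R-side
    // sort), then leftmost, then forward strand
    if (ref_id < best.ref) better = true;
    else if (ref_id == best.ref) {
      int start = (int)(diag + lo);
      if (start < best.start) better = true;
      else if (start == best.start && strand < best.strand) better = true;
    }
  }
  if (better) {
    best.ok = true; best.ref = ref_id;
    best.start = (int)(diag + lo); best.end = (int)(diag + hi);
    best.matches = matches; best.overlap = overlap; best.strand = strand;
  }
}

static void place_read(const SeedIndex& ix, const std::string& fwd,
                       double min_match_frac, int step, int max_diags,
                       std::vector<std::vector<int> >& depth,
                       long& placed, long& unplaced) {
  const int k = ix.seed_len;
  const uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  std::string rev = fwd;
  revcomp_inplace(rev);
  const std::string* strands[2] = { &fwd, &rev };
  Placement best; best.ok = false; best.matches = -1; best.ref = 1 << 30; best.start = 1 << 30; best.strand = 0;
  for (int st = 0; st < 2; ++st) {
    const std::string& rd = *strands[st];
    if ((int)rd.size() < k) continue;
    // votes: key = (ref << 33) | (diag + 2^31)
    std::unordered_map<uint64_t, int> votes;
    uint64_t w = 0; int valid = 0;
    int next_probe = k - 1;
    for (int i = 0; i < (int)rd.size(); ++i) {
      int b = b2i(rd[i]);
      if (b < 0) { valid = 0; w = 0; continue; }
      w = ((w << 2) | (uint64_t)b) & mask;
      ++valid;
      if (valid >= k && i >= next_probe) {
        next_probe = i + step;
        std::unordered_map<uint64_t, std::vector<uint64_t> >::const_iterator it = ix.pos.find(w);
        if (it == ix.pos.end()) continue;
        const std::vector<uint64_t>& pv = it->second;
        int qp = i - k + 1;
        for (size_t m = 0; m < pv.size(); ++m) {
          int ref = (int)(pv[m] >> 32);
          long sp = (long)(pv[m] & 0xffffffffULL);
          uint64_t key = ((uint64_t)ref << 33) | (uint64_t)(sp - qp + 2147483648LL);
          votes[key]++;
        }
      }
    }
    if (votes.empty()) continue;
    // rank candidate diagonals by vote count, evaluate the top max_diags
    std::vector<std::pair<int, uint64_t> > cand;
    cand.reserve(votes.size());
    for (std::unordered_map<uint64_t, int>::const_iterator it = votes.begin(); it != votes.end(); ++it)
      cand.push_back(std::make_pair(-it->second, it->first));
    int ncand = std::min((int)cand.size(), max_diags);
    std::partial_sort(cand.begin(), cand.begin() + ncand, cand.end());
    for (int c = 0; c < ncand; ++c) {
      uint64_t key = cand[c].second;
      int ref = (int)(key >> 33);
      long diag = (long)(key & 0x1ffffffffULL) - 2147483648LL;
      eval_diag(rd, ix.seqs[ref], ref, diag, st, best);
    }
  }
  if (best.ok && best.matches >= min_match_frac * best.overlap) {
    std::vector<int>& d = depth[best.ref];
    for (int p = best.start; p < best.end; ++p) ++d[p];
    ++placed;
  } else {
    ++unplaced;
  }
}

// [[Rcpp::export]]
List cpp_map_reads(SEXP ptr_, CharacterVector reads, double min_match_frac,
                   int step, int max_diags) {
  XPtr<SeedIndex> ix(ptr_);
  std::vector<std::vector<int> > depth(ix->seqs.size());
  for (size_t r = 0; r < ix->seqs.size(); ++r)
    depth[r].assign(ix->seqs[r].size(), 0);
  long placed = 0, unplaced = 0;
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    std::string rd = as<std::string>(reads[i]);
    place_read(*ix, rd, min_match_frac, step, max_diags, depth, placed, unplaced);
  }
  List dl(depth.size());
  for (size_t r = 0; r < depth.size(); ++r)
    dl[r] = IntegerVector(depth[r].begin(), depth[r].end());
  return List::create(_["depth"] = dl, _["placed"] = (double)placed,
                      _["unplaced"] = (double)unplaced);
}

// Stream FASTQ files directly through the placer (avoids materializing
// millions of read strings in R).
// [[Rcpp::export]]
List cpp_map_fastq(SEXP ptr_, CharacterVector files, double min_match_frac,
                   int step, int max_diags) {
  XPtr<SeedIndex> ix(ptr_);
  std::vector<std::vector<int> > depth(ix->seqs.size());
  for (size_t r = 0; r < ix->seqs.size(); ++r)
    depth[r].assign(ix->seqs[r].size(), 0);
  long placed = 0, unplaced = 0;
  for (R_xlen_t f = 0; f < files.size(); ++f) {
    std::string path = as<std::string>(files[f]);
    std::ifstream in(path.c_str());
    if (!in) stop("cannot open reads file '%s'", path.c_str());
    std::string hdr, seq, sep, qual;
    long rec = 0;
    while (std::getline(in, hdr)) {
      if (hdr.empty()) continue;
      ++rec;
      if (hdr[0] != '@')
        stop("malformed FASTQ record %ld in '%s'", rec, path.c_str());
      if (!std::getline(in, seq) || !std::getline(in, sep) || !std::getline(in, qual))
        stop("malformed FASTQ record %ld in '%s': truncated", rec, path.c_str());
      place_read(*ix, seq, min_match_frac, step, max_diags, depth, placed, unplaced);
    }
  }
  List dl(depth.size());
  for (size_t r = 0; r < depth.size(); ++r)
    dl[r] = IntegerVector(depth[r].begin(), depth[r].end());
  return List::create(_["depth"] = dl, _["placed"] = (double)placed,
                      _["unplaced"] = (double)unplaced);
}
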