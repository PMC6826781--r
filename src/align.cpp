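// Seed-and-extend local alignment: exact word seeds, seeds grouped by
// diagonal, each group extended by banded affine-gap Smith-Waterman.
// Coordinates are 0-based half-open on input orientation. Two entry points:
// cpp_local_align (one pair, one orientation; strand handling in R) and
// cpp_align_pairs (all query x subject pairs, both strands, subject word
// index built once per subject).
#include <Rcpp.h>
#include <cstdint>
#include <cstring>
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

static std::string revcomp_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) {
    switch (r[i]) {
      case 'A': case 'a': r[i] = 'T'; break;
      case 'C': case 'c': r[i] = 'G'; break;
      case 'G': case 'g': r[i] = 'C'; break;
      case 'T': case 't': r[i] = 'A'; break;
      default: r[i] = 'N';
    }
  }
  return r;
}

struct Seed { int q, s, d; };
struct Hit {
  int qstart, qend, sstart, send;
  double score;
  int matches, columns;
  int strand;  // 0 = forward, 1 = reverse (query was reverse-complemented)
};

struct AlignOpts {
  int word_size;
  double match, mismatch, gap_open, gap_ext;
  int band_extra, max_seed_gap;
  double min_score;
  int max_word_occ, max_clusters;
};

typedef std::unordered_map<uint32_t, std::vector<int> > WordIndex;

static void index_words(const std::string& s, int word_size, WordIndex& idx) {
  const uint32_t mask = (1U << (2 * word_size)) - 1;
  uint32_t w = 0; int valid = 0;
  const int sn = (int)s.size();
  for (int j = 0; j < sn; ++j) {
    int b = b2i(s[j]);
    if (b < 0) { valid = 0; w = 0; continue; }
    w = ((w << 2) | (uint32_t)b) & mask;
    if (++valid >= word_size) idx[w].push_back(j - word_size + 1);
  }
}

// Banded local alignment of query[qlo,qhi) vs subject[slo,shi) with diagonal
// (absolute d = s - q) restricted to [dlo_abs, dhi_abs]. Returns best local hit.
static bool banded_sw(const char* q, const char* s,
                      int qlo, int qhi, int slo, int shi,
                      int dlo_abs, int dhi_abs, const AlignOpts& o_,
                      Hit& out) {
  const int qw = qhi - qlo;
  if (qw <= 0 || shi - slo <= 0) return false;
  const int dlo = dlo_abs - (slo - qlo);
  const int dhi = dhi_abs - (slo - qlo);
  const int W = dhi - dlo + 1;
  if (W <= 0 || W > 512) return false;
  const double NEG = -1e18;
  std::vector<double> Hprev(W, 0.0), Hcur(W, 0.0), Eprev(W, NEG), Ecur(W, NEG);
  std::vector<uint8_t> tb((size_t)(qw + 1) * W, 0);
  double best = 0.0;
  int bi = -1, bo = -1;
  for (int i = 1; i <= qw; ++i) {
    double Fcur = NEG;
    for (int o = 0; o < W; ++o) {
      const int j = i + dlo + o;  // subject chars consumed at this cell
      uint8_t dir = 0;
      double h = 0.0;
      if (j < 1 || j > shi - slo) { Hcur[o] = NEG; Ecur[o] = NEG; continue; }
      double hd = Hprev[o];
      if (hd > NEG / 2) {
        const char qa = q[qlo + i - 1], sb = s[slo + j - 1];
        const bool eq = (b2i(qa) >= 0) && (b2i(qa) == b2i(sb));
        double cand = hd + (eq ? o_.match : o_.mismatch);
        if (cand > h) { h = cand; dir = 1; }
      }
      double e = NEG;
      uint8_t ebit = 0;
      if (o + 1 < W) {
        double fromH = Hprev[o + 1] > NEG / 2 ? Hprev[o + 1] + o_.gap_open : NEG;
        double fromE = Eprev[o + 1] > NEG / 2 ? Eprev[o + 1] + o_.gap_ext : NEG;
        e = std::max(fromH, fromE);
        ebit = (fromE >= fromH) ? 1 : 0;
      }
      Ecur[o] = e;
      if (e > h) { h = e; dir = 2; }
      double f = NEG;
      uint8_t fbit = 0;
      if (o - 1 >= 0) {
        double fromH = Hcur[o - 1] > NEG / 2 ? Hcur[o - 1] + o_.gap_open : NEG;
        double fromF = Fcur > NEG / 2 ? Fcur + o_.gap_ext : NEG;
        f = std::max(fromH, fromF);
        fbit = (fromF >= fromH) ? 1 : 0;
      }
      Fcur = f;
      if (f > h) { h = f; dir = 3; }
      if (h <= 0.0) { h = 0.0; dir = 0; }
      Hcur[o] = h;
      tb[(size_t)i * W + o] = dir | (ebit << 2) | (fbit << 3);
      if (h > best) { best = h; bi = i; bo = o; }
    }
    std::swap(Hprev, Hcur);
    std::swap(Eprev, Ecur);
  }
  if (bi < 0 || best <= 0.0) return false;
  int i = bi, o = bo;
  int state = 0;
  int matches = 0, columns = 0;
  int qend = qlo + i;
  int send = slo + i + dlo + o;
  int qcur = qend, scur = send;
  for (;;) {
    uint8_t t = tb[(size_t)i * W + o];
    if (state == 0) {
      uint8_t dir = t & 3;
      if (dir == 0) break;
      if (dir == 1) {
        const char qa = q[qcur - 1], sb = s[scur - 1];
        if (b2i(qa) >= 0 && b2i(qa) == b2i(sb)) ++matches;
        ++columns; --qcur; --scur; --i;
      } else if (dir == 2) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 1) {
      uint8_t ebit = (t >> 2) & 1;
      ++columns; --qcur; --i; ++o;
      state = ebit ? 1 : 0;
    } else {
      uint8_t fbit = (t >> 3) & 1;
      ++columns; --scur; --o;
      state = fbit ? 2 : 0;
    }
    if (i <= 0 || o < 0 || o >= W) break;
  }
  out.qstart = qcur; out.qend = qend;
  out.sstart = scur; out.send = send;
  out.score = best; out.matches = matches; out.columns = columns;
  return out.columns > 0;
}

// Seed, cluster by diagonal, extend; hits appended to `hits`.
static void seed_extend(const std::string& query, const std::string& subject,
                        const WordIndex& idx, const AlignOpts& o, int strand,
                        std::vector<Hit>& hits) {
  const int qn = (int)query.size(), sn = (int)subject.size();
  if (qn < o.word_size || sn < o.word_size) return;
  const uint32_t mask = (1U << (2 * o.word_size)) - 1;
  std::vector<Seed> seeds;
  {
    uint32_t w = 0; int valid = 0;
    for (int i = 0; i < qn; ++i) {
      int b = b2i(query[i]);
      if (b < 0) { valid = 0; w = 0; continue; }
      w = ((w << 2) | (uint32_t)b) & mask;
      if (++valid >= o.word_size) {
        WordIndex::const_iterator it = idx.find(w);
        if (it == idx.end()) continue;
        const std::vector<int>& pos = it->second;
        int take = (o.max_word_occ > 0 && (int)pos.size() > o.max_word_occ)
          ? o.max_word_occ : (int)pos.size();
        int qp = i - o.word_size + 1;
        for (int m = 0; m < take; ++m) {
          Seed sd; sd.q = qp; sd.s = pos[m]; sd.d = pos[m] - qp;
          seeds.push_back(sd);
          if (seeds.size() > 4000000u) break;
        }
        if (seeds.size() > 4000000u) break;
      }
    }
  }
  std::sort(seeds.begin(), seeds.end(), [](const Seed& a, const Seed& b) {
    if (a.d != b.d) return a.d < b.d;
    return a.s < b.s;
  });
  size_t i0 = 0;
  int nclust = 0;
  while (i0 < seeds.size() && nclust < o.max_clusters) {
    size_t i1 = i0 + 1;
    int dmin = seeds[i0].d, dmax = seeds[i0].d;
    int qmin = seeds[i0].q, qmax = seeds[i0].q;
    int smin = seeds[i0].s, smax = seeds[i0].s;
    while (i1 < seeds.size()) {
      const Seed& sd = seeds[i1];
      if (sd.d - dmax > o.band_extra) break;
      if (sd.d == dmax && sd.d == seeds[i1 - 1].d &&
          sd.s - seeds[i1 - 1].s > o.max_seed_gap) break;
      if (std::max(sd.d, dmax) - std::min(sd.d, dmin) > 2 * o.band_extra) break;
      dmin = std::min(dmin, sd.d); dmax = std::max(dmax, sd.d);
      qmin = std::min(qmin, sd.q); qmax = std::max(qmax, sd.q);
      smin = std::min(smin, sd.s); smax = std::max(smax, sd.s);
      ++i1;
    }
    ++nclust;
    const int ext = 60;
    int qlo = std::max(0, qmin - ext), qhi = std::min(qn, qmax + o.word_size + ext);
    int slo = std::max(0, smin - ext), shi = std::min(sn, smax + o.word_size + ext);
    Hit h;
    if (banded_sw(query.c_str(), subject.c_str(), qlo, qhi, slo, shi,
                  dmin - o.band_extra, dmax + o.band_extra, o, h)) {
      if (h.score >= o.min_score) { h.strand = strand; hits.push_back(h); }
    }
    i0 = i1;
  }
}

// Drop hits overlapping a better hit in both query and subject (>50% of the
// smaller extent on each axis).
static void dedupe_hits(std::vector<Hit>& hits) {
  std::sort(hits.begin(), hits.end(), [](const Hit& a, const Hit& b) {
    if (a.score != b.score) return a.score > b.score;
    if (a.qstart != b.qstart) return a.qstart < b.qstart;
    return a.sstart < b.sstart;
  });
  std::vector<Hit> kept;
  for (size_t i = 0; i < hits.size(); ++i) {
    bool drop = false;
    for (size_t j = 0; j < kept.size(); ++j) {
      int qo = std::min(hits[i].qend, kept[j].qend) - std::max(hits[i].qstart, kept[j].qstart);
      int so = std::min(hits[i].send, kept[j].send) - std::max(hits[i].sstart, kept[j].sstart);
      int qlen = std::min(hits[i].qend - hits[i].qstart, kept[j].qend - kept[j].qstart);
      int slen = std::min(hits[i].send - hits[i].sstart, kept[j].send - kept[j].sstart);
      if (qlen > 0 && slen > 0 && qo > qlen / 2 && so > slen / 2) { drop = true; break; }
    }
    if (!drop) kept.push_back(hits[i]);
  }
  hits.swap(kept);
}

// [[Rcpp::export]]
DataFrame cpp_local_align(std::string query, std::string subject,
                          int word_size, double match, double mismatch,
                          double gap_open, double gap_ext,
                          int band_extra, int max_seed_gap,
                          double min_score, int max_word_occ,
                          int max_clusters) {
  AlignOpts o;
  o.word_size = word_size; o.match = match; o.mismatch = mismatch;
  o.gap_open = gap_open; o.gap_ext = gap_ext; o.band_extra = band_extra;
  o.max_seed_gap = max_seed_gap; o.min_score = min_score;
  o.max_word_occ = max_word_occ; o.max_clusters = max_clusters;
  std::vector<Hit> hits;
  if ((int)query.size() >= word_size && (int)subject.size() >= word_size &&
      word_size >= 4 && word_size <= 15) {
    WordIndex idx;
    index_words(subject, word_size, idx);
    seed_extend(query, subject, idx, o, 0, hits);
    dedupe_hits(hits);
  }
  const int n = (int)hits.size();
  IntegerVector qstart(n), qend(n), sstart(n), send(n), matches(n), columns(n);
  NumericVector score(n);
  for (int i = 0; i < n; ++i) {
    qstart[i] = hits[i].qstart; qend[i] = hits[i].qend;
    sstart[i] = hits[i].sstart; send[i] = hits[i].send;
    score[i] = hits[i].score; matches[i] = hits[i].matches; columns[i] = hits[i].columns;
  }
  return DataFrame::create(_["qstart"] = qstart, _["qend"] = qend,
                           _["sstart"] = sstart, _["send"] = send,
                           _["score"] = score, _["matches"] = matches,
                           _["columns"] = columns);
}

// All query x subject pairs, both strands. Per pair with at least one hit,
// reports the best-scoring hit plus summary columns used by the library
// operations: the maximum identity among hits spanning >= min_cols
// alignment columns, and the count of such hits.
// [[Rcpp::export]]
DataFrame cpp_align_pairs(CharacterVector queries, CharacterVector subjects,
                          int word_size, double match, double mismatch,
                          double gap_open, double gap_ext,
                          int band_extra, int max_seed_gap,
                          double min_score, int max_word_occ,
                          int max_clusters, int min_cols) {
  AlignOpts o;
  o.word_size = word_size; o.match = match; o.mismatch = mismatch;
  o.gap_open = gap_open; o.gap_ext = gap_ext; o.band_extra = band_extra;
  o.max_seed_gap = max_seed_gap; o.min_score = min_score;
  o.max_word_occ = max_word_occ; o.max_clusters = max_clusters;
  std::vector<int> r_qi, r_sj, r_qs, r_qe, r_ss, r_se, r_match, r_cols, r_nmin;
  std::vector<double> r_score, r_bestid;
  std::vector<int> r_strand;
  const int nq = queries.size(), ns = subjects.size();
  std::vector<std::string> qf(nq), qr(nq);
  for (int i = 0; i < nq; ++i) {
    qf[i] = as<std::string>(queries[i]);
    qr[i] = revcomp_str(qf[i]);
  }
  for (int j = 0; j < ns; ++j) {
    std::string subj = as<std::string>(subjects[j]);
    if ((int)subj.size() < word_size) continue;
    WordIndex idx;
    index_words(subj, word_size, idx);
    for (int i = 0; i < nq; ++i) {
      if ((int)qf[i].size() < word_size) continue;
      std::vector<Hit> hits;
      seed_extend(qf[i], subj, idx, o, 0, hits);
      seed_extend(qr[i], subj, idx, o, 1, hits);
      // map reverse-strand query coordinates back to the forward query
      const int qlen = (int)qf[i].size();
      for (size_t m = 0; m < hits.size(); ++m) {
        if (hits[m].strand == 1) {
          int qs = qlen - hits[m].qend, qe = qlen - hits[m].qstart;
          hits[m].qstart = qs; hits[m].qend = qe;
        }
      }
      dedupe_hits(hits);
      if (hits.empty()) continue;
      double best_id = -1.0;
      int n_min = 0;
      for (size_t m = 0; m < hits.size(); ++m) {
        if (hits[m].columns >= min_cols) {
          ++n_min;
          double id = (double)hits[m].matches / hits[m].columns;
          if (id > best_id) best_id = id;
        }
      }
      const Hit& b = hits[0];
      r_qi.push_back(i + 1); r_sj.push_back(j + 1);
      r_qs.push_back(b.qstart); r_qe.push_back(b.qend);
      r_ss.push_back(b.sstart); r_se.push_back(b.send);
      r_strand.push_back(b.strand);
      r_score.push_back(b.score);
      r_match.push_back(b.matches); r_cols.push_back(b.columns);
      r_bestid.push_back(best_id); r_nmin.push_back(n_min);
    }
  }
  return DataFrame::create(
    _["query"] = r_qi, _["subject"] = r_sj,
    _["qstart"] = r_qs, _["qend"] = r_qe,
    _["sstart"] = r_ss, _["send"] = r_se,
    _["strand"] = r_strand, _["score"] = r_score,
    _["matches"] = r_match, _["columns"] = r_cols,
    _["best_identity_min_cols"] = r_bestid,
    _["n_hits_min_cols"] = r_nmin);
}
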