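// Split-read alignment against a tandem-doubled circular reference.
//
// Exact k-mer seeding plus mismatch-tolerant ungapped extension.  A read
// is reported as contiguous when one anchor covers (almost) the whole
// read, or as a two-anchor split when its two flanks anchor at distinct
// reference loci with a positive reference gap.  Coordinates returned are
// 1-based inclusive on the doubled reference; the R layer canonicalizes
// them onto the circle.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
using namespace Rcpp;

static inline int base2bits(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default: return -1;
  }
}

struct Anchor {
  int rl, rr;   // read interval, 0-based inclusive
  int ql, qr;   // reference interval, 0-based inclusive (doubled ref)
  int len() const { return rr - rl + 1; }
};

typedef std::unordered_map<uint32_t, std::vector<int> > KIndex;

static void build_index(const std::string &ref, int k, KIndex &idx) {
  const int n = (int)ref.size();
  uint32_t key = 0, mask = (k == 16) ? 0xFFFFFFFFu : ((1u << (2 * k)) - 1u);
  int valid = 0;
  for (int i = 0; i < n; ++i) {
    int b = base2bits(ref[i]);
    if (b < 0) { valid = 0; key = 0; continue; }
    key = ((key << 2) | (uint32_t)b) & mask;
    if (++valid >= k) idx[key].push_back(i - k + 1);
  }
}

// maximal ungapped extension around read[o] ~ ref[p], tolerating up to
// max_mm mismatches in total; the returned interval ends on exact matches
static bool extend(const std::string &rd, const std::string &ref,
                   int o, int p, int max_mm, Anchor &out) {
  const int n = (int)rd.size(), m = (int)ref.size();
  int mm = 0;
  // rightward
  int i = o, q = p, last_r = -1, last_q = -1;
  while (i < n && q < m) {
    if (rd[i] == ref[q]) { last_r = i; last_q = q; }
    else if (++mm > max_mm) break;
    ++i; ++q;
  }
  if (last_r < 0) return false;
  int rr = last_r, qr = last_q;
  // leftward (mismatch budget shared)
  int first_r = o, first_q = p;
  i = o - 1; q = p - 1;
  while (i >= 0 && q >= 0) {
    if (rd[i] == ref[q]) { first_r = i; first_q = q; }
    else if (++mm > max_mm) break;
    --i; --q;
  }
  out.rl = first_r; out.rr = rr; out.ql = first_q; out.qr = qr;
  return out.len() > 0;
}

static bool best_anchor(const std::string &rd, const std::string &ref,
                        const KIndex &idx, int k, int max_mm,
                        const std::vector<int> &offsets, Anchor &best) {
  const int max_hits = 64;
  bool found = false;
  for (size_t oi = 0; oi < offsets.size(); ++oi) {
    int o = offsets[oi];
    if (o < 0 || o + k > (int)rd.size()) continue;
    uint32_t key = 0;
    bool ok = true;
    for (int j = 0; j < k; ++j) {
      int b = base2bits(rd[o + j]);
      if (b < 0) { ok = false; break; }
      key = (key << 2) | (uint32_t)b;
    }
    if (!ok) continue;
    KIndex::const_iterator it = idx.find(key);
    if (it == idx.end()) continue;
    const std::vector<int> &hits = it->second;
    int nh = (int)hits.size();
    if (nh > max_hits) nh = max_hits;
    for (int h = 0; h < nh; ++h) {
      Anchor a;
      if (!extend(rd, ref, o, hits[h], max_mm, a)) continue;
      if (!found || a.len() > best.len() ||
          (a.len() == best.len() && a.ql < best.ql)) {
        best = a; found = true;
      }
    }
    if (found) return true;  // seed hit at this offset: take it
  }
  return found;
}

static std::string revcomp(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) {
    switch (r[i]) {
    case 'A': r[i] = 'T'; break;
    case 'C': r[i] = 'G'; break;
    case 'G': r[i] = 'C'; break;
    case 'T': r[i] = 'A'; break;
    default: r[i] = 'N';
    }
  }
  return r;
}

// attempt alignment of one oriented read; returns type 0/1/2
static int align_one(const std::string &rd, const std::string &ref,
                     const KIndex &idx, int k, int min_anchor, int max_mm,
                     int L, Anchor &a1, Anchor &a2) {
  const int n = (int)rd.size();
  std::vector<int> offs;
  for (int o = 0; o + k <= n && o <= 3 * k; o += k / 2) offs.push_back(o);
  if (!best_anchor(rd, ref, idx, k, max_mm, offs, a1)) return 0;
  if (a1.len() >= n - 4) return 1;   // covers the read: contiguous
  if (a1.len() < min_anchor) return 0;
  // right anchor, seeded from the read's tail
  std::vector<int> roffs;
  for (int o = n - k; o >= 0 && o >= n - k - 3 * k; o -= k / 2)
    roffs.push_back(o);
  // collect candidate right anchors across tail seeds; pick min positive gap
  const int max_hits = 64;
  bool found = false;
  Anchor best;
  long best_gap = 0;
  int best_b_final = -1;
  const int a1_rr = a1.rr;   // left anchor's tolerant extent (fixed)
  const long d1 = (long)a1.ql - a1.rl;
  for (size_t oi = 0; oi < roffs.size(); ++oi) {
    int o = roffs[oi];
    if (o <= a1.rl || o + k > n) continue;
    uint32_t key = 0;
    bool ok = true;
    for (int j = 0; j < k; ++j) {
      int b = base2bits(rd[o + j]);
      if (b < 0) { ok = false; break; }
      key = (key << 2) | (uint32_t)b;
    }
    if (!ok) continue;
    KIndex::const_iterator it = idx.find(key);
    if (it == idx.end()) continue;
    const std::vector<int> &hits = it->second;
    int nh = (int)hits.size();
    if (nh > max_hits) nh = max_hits;
    for (int h = 0; h < nh; ++h) {
      Anchor a;
      if (!extend(rd, ref, o, hits[h], max_mm, a)) continue;
      if (a.rr < n - 4) continue;         // must reach the read's end
      if (a.rl > a1_rr + 1) continue;     // junction must be read-contiguous
      long d2 = (long)a.ql - a.rl;        // alignment diagonals
      long gap = d2 - d1;                 // implied deletion length
      if (gap < 1 || gap > L - 1) continue; // a deletant retains >= 1 base
      // place the breakpoint where total matches to both loci are
      // maximal: b = last read index assigned to the left locus
      int lo = a.rl, hi = a1_rr;
      long s = 0;
      for (int i = lo; i <= hi; ++i)
        if ((long)i + d2 < (long)ref.size() && rd[i] == ref[i + d2]) ++s;
      long best_s = s;
      int best_b = lo - 1;
      for (int b = lo; b <= hi; ++b) {
        if ((long)b + d1 < (long)ref.size() && rd[b] == ref[b + d1]) ++s;
        if ((long)b + d2 < (long)ref.size() && rd[b] == ref[b + d2]) --s;
        if (s >= best_s) { best_s = s; best_b = b; }
      }
      int b = best_b;
      if (b - a1.rl + 1 < min_anchor) continue;  // left part too short
      if (a.rr - b < min_anchor) continue;       // right part too short
      Anchor a2c;
      a2c.rl = b + 1; a2c.rr = a.rr;
      a2c.ql = (int)(b + 1 + d2); a2c.qr = a.qr;
      if (!found || gap < best_gap) {
        best = a2c; best_gap = gap; found = true;
        best_b_final = b;
      }
    }
    if (found) break;
  }
  if (!found) {
    // no junction: contiguous when the anchor covers all but a flank too
    // short to call anyway, else unaligned
    return (a1.len() >= n - min_anchor + 1) ? 1 : 0;
  }
  a1.rr = best_b_final;
  a1.qr = (int)(best_b_final + d1);
  a2 = best;
  return 2;
}

// [[Rcpp::export]]
List cpp_align_batch(CharacterVector reads, std::string ref2, int L,
                     int k, int min_anchor, int max_mm) {
  KIndex idx;
  build_index(ref2, k, idx);
  const int n = reads.size();
  IntegerVector type(n), strand(n), s1(n), e1(n), s2(n), e2(n), alen(n);
  for (int i = 0; i < n; ++i) {
    std::string rd = as<std::string>(reads[i]);
    Anchor a1, a2;
    int t = align_one(rd, ref2, idx, k, min_anchor, max_mm, L, a1, a2);
    int str = 1;
    if (t == 0) {
      std::string rc = revcomp(rd);
      t = align_one(rc, ref2, idx, k, min_anchor, max_mm, L, a1, a2);
      str = -1;
    }
    type[i] = t; strand[i] = str;
    if (t >= 1) { s1[i] = a1.ql + 1; e1[i] = a1.qr + 1; }
    if (t == 2) { s2[i] = a2.ql + 1; e2[i] = a2.qr + 1; }
    alen[i] = (t == 1) ? a1.len() : (t == 2 ? a1.len() + a2.len() : 0);
  }
  return List::create(_["type"] = type, _["strand"] = strand,
                      _["s1"] = s1, _["e1"] = e1,
                      _["s2"] = s2, _["e2"] = e2, _["alen"] = alen);
}
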