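#ifndef XENOTRACE_CORE_H
#define XENOTRACE_CORE_H

#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <vector>
#include <unordered_map>
#include <algorithm>

// 2-bit base encoding; 4 marks N / anything else. N never matches and
// never contributes a k-mer.
static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return 4;
  }
}

static const char CODE2BASE[5] = {'A', 'C', 'G', 'T', 'N'};

static inline std::vector<uint8_t> encode_seq(const char* s, size_t n) {
  std::vector<uint8_t> out(n);
  for (size_t i = 0; i < n; ++i) out[i] = (uint8_t) base_code(s[i]);
  return out;
}

static inline std::vector<uint8_t> revcomp_codes(const std::vector<uint8_t>& v) {
  std::vector<uint8_t> out(v.size());
  for (size_t i = 0; i < v.size(); ++i) {
    uint8_t c = v[v.size() - 1 - i];
    out[i] = (c > 3) ? 4 : (uint8_t)(3 - c);
  }
  return out;
}

// reverse complement of a 2-bit packed k-mer (k <= 31, odd)
static inline uint64_t revcomp_bits(uint64_t x, int k) {
  x = ~x;
  x = ((x >> 2) & 0x3333333333333333ULL) | ((x & 0x3333333333333333ULL) << 2);
  x = ((x >> 4) & 0x0F0F0F0F0F0F0F0FULL) | ((x & 0x0F0F0F0F0F0F0F0FULL) << 4);
  x = ((x >> 8) & 0x00FF00FF00FF00FFULL) | ((x & 0x00FF00FF00FF00FFULL) << 8);
  x = ((x >> 16) & 0x0000FFFF0000FFFFULL) | ((x & 0x0000FFFF0000FFFFULL) << 16);
  x = (x >> 32) | (x << 32);
  return x >> (64 - 2 * k);
}

static inline std::string decode_kmer(uint64_t x, int k) {
  std::string s(k, 'N');
  for (int i = k - 1; i >= 0; --i) { s[i] = CODE2BASE[x & 3ULL]; x >>= 2; }
  return s;
}

// Visit every N-free k-mer of a coded sequence. f(pos, fwd, rev).
template <typename F>
static inline void for_each_kmer(const std::vector<uint8_t>& codes, int k, F f) {
  const uint64_t mask = (2 * k == 64) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
  const int shift = 2 * (k - 1);
  uint64_t fwd = 0, rev = 0;
  int run = 0;
  for (size_t i = 0; i < codes.size(); ++i) {
    int c = codes[i];
    if (c > 3) { run = 0; fwd = 0; rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t) c) & mask;
    rev = (rev >> 2) | ((uint64_t)(3 - c) << shift);
    if (++run >= k) f((long)(i + 1 - k), fwd, rev);
  }
}

// ---------------------------------------------------------------------------
// Banded local (Smith-Waterman-style) alignment restricted to a diagonal band.
// Query rows run over [q0, q1); subject position for cell (i, t) is
// j = (q0 + i - 1) + diag + (t - band). Linear gap penalty.
// Coordinates in the result are 0-based half-open.
// ---------------------------------------------------------------------------
struct Aln {
  int score = 0;
  int matches = 0;
  int columns = 0;
  long q_beg = 0, q_end = 0, s_beg = 0, s_end = 0;
  bool valid = false;
};

// Per-column alignment detail (optional banded_local output, query order).
// qpos/spos are -1 for columns that do not consume that sequence.
struct AlnCols {
  std::vector<uint8_t> is_match;
  std::vector<long> qpos, spos;
};

static inline Aln banded_local(const uint8_t* q, long q0, long q1,
                               const uint8_t* s, long slen,
                               long diag, int band,
                               int match, int mismatch, int gap,
                               AlnCols* cols = 0) {
  Aln res;
  const long n = q1 - q0;
  if (n <= 0 || slen <= 0) return res;
  const int W = 2 * band + 1;
  std::vector<int> Hprev((size_t) W, 0), Hcur((size_t) W, 0);
  std::vector<uint8_t> tb((size_t)(n + 1) * W, 0);  // 0 stop, 1 diag, 2 up, 3 left
  int best = 0; long bi = -1; int bt = -1;
  for (long i = 1; i <= n; ++i) {
    const long qpos = q0 + i - 1;
    const int qc = q[qpos];
    for (int t = 0; t < W; ++t) {
      const long j = qpos + diag + (long)(t - band);
      if (j < 0 || j >= slen) { Hcur[t] = 0; continue; }
      const int sc = s[j];
      const int sub = (qc == sc && qc < 4) ? match : mismatch;
      int h = 0; uint8_t dir = 0;
      const int hd = Hprev[t] + sub;                       // consume both
      if (hd > h) { h = hd; dir = 1; }
      if (t + 1 < W) {
        const int hu = Hprev[t + 1] - gap;                 // gap in subject
        if (hu > h) { h = hu; dir = 2; }
      }
      if (t - 1 >= 0) {
        const int hl = Hcur[t - 1] - gap;                  // gap in query
        if (hl > h) { h = hl; dir = 3; }
      }
      Hcur[t] = h;
      tb[(size_t) i * W + t] = dir;
      if (h > best) { best = h; bi = i; bt = t; }
    }
    std::swap(Hprev, Hcur);
  }
  if (best <= 0) return res;

  // traceback
  long i = bi; int t = bt;
  long qmin = q0 + bi, smin = (q0 + bi - 1) + diag + (bt - band) + 1;
  int matches = 0, columns = 0;
  if (cols) { cols->is_match.clear(); cols->qpos.clear(); cols->spos.clear(); }
  while (i >= 1) {
    const uint8_t dir = tb[(size_t) i * W + t];
    if (dir == 0) break;
    const long qpos = q0 + i - 1;
    const long j = qpos + diag + (long)(t - band);
    ++columns;
    if (dir == 1) {
      const bool m = (q[qpos] == s[j] && q[qpos] < 4);
      if (m) ++matches;
      if (cols) { cols->is_match.push_back(m ? 1 : 0);
                  cols->qpos.push_back(qpos); cols->spos.push_back(j); }
      qmin = qpos; smin = j;
      --i;
    } else if (dir == 2) {
      if (cols) { cols->is_match.push_back(0);
                  cols->qpos.push_back(qpos); cols->spos.push_back(-1); }
      qmin = qpos;
      --i; ++t;
    } else {
      if (cols) { cols->is_match.push_back(0);
                  cols->qpos.push_back(-1); cols->spos.push_back(j); }
      smin = j;
      --t;
    }
  }
  if (cols) {
    std::reverse(cols->is_match.begin(), cols->is_match.end());
    std::reverse(cols->qpos.begin(), cols->qpos.end());
    std::reverse(cols->spos.begin(), cols->spos.end());
  }
  res.score = best;
  res.matches = matches;
  res.columns = columns;
  res.q_beg = qmin;
  res.q_end = q0 + bi;
  res.s_beg = smin;
  res.s_end = (q0 + bi - 1) + diag + (long)(bt - band) + 1;
  res.valid = true;
  return res;
}

// ---------------------------------------------------------------------------
// Canonical k-mer index over a contig set (the subtraction / linking target).
// Each canonical k-mer stores packed occurrences:
//   (contig_idx << 34) | (pos << 1) | fwd_is_canonical
// ---------------------------------------------------------------------------
struct KmerIndex {
  int k = 0;
  std::vector<std::string> names;
  std::vector<std::vector<uint8_t> > seqs;
  std::unordered_map<uint64_t, std::vector<uint64_t> > occ;
  uint64_t total_len = 0;
};

#endif
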