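#include "core.h"
using namespace Rcpp;

// De Bruijn graph in canonical k-mer form: sorted key array plus
// multiplicity counts. Nodes are the (k-1)-mer prefixes/suffixes implied by
// the k-mers; unitigs are maximal non-branching walks. Sorted storage makes
// every traversal deterministic regardless of read input order.
struct DBG {
  int k = 0;
  std::vector<uint64_t> keys;    // canonical k-mers, ascending
  std::vector<uint32_t> counts;
};

static inline long dbg_find(const DBG& g, uint64_t canon) {
  std::vector<uint64_t>::const_iterator it =
    std::lower_bound(g.keys.begin(), g.keys.end(), canon);
  if (it == g.keys.end() || *it != canon) return -1;
  return (long)(it - g.keys.begin());
}

static inline uint64_t kmask(int k) {
  return (2 * k == 64) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
}

// unique forward extension of oriented k-mer f; returns extension count,
// stores the (single) extension when count == 1
static inline int dbg_succ(const DBG& g, uint64_t f, uint64_t* out) {
  const uint64_t mask = kmask(g.k);
  int n = 0;
  for (uint64_t b = 0; b < 4; ++b) {
    const uint64_t nf = ((f << 2) | b) & mask;
    const uint64_t canon = std::min(nf, revcomp_bits(nf, g.k));
    if (dbg_find(g, canon) >= 0) { ++n; *out = nf; }
  }
  return n;
}

static inline int dbg_pred(const DBG& g, uint64_t f, uint64_t* out) {
  const int shift = 2 * (g.k - 1);
  int n = 0;
  for (uint64_t b = 0; b < 4; ++b) {
    const uint64_t pf = (b << shift) | (f >> 2);
    const uint64_t canon = std::min(pf, revcomp_bits(pf, g.k));
    if (dbg_find(g, canon) >= 0) { ++n; *out = pf; }
  }
  return n;
}

// [[Rcpp::export]]
SEXP dbg_build_cpp(CharacterVector reads, int k) {
  if (k < 15 || k > 31 || k % 2 == 0)
    stop("assembly k must be an odd integer in [15, 31]");
  DBG* g = new DBG();
  g->k = k;
  std::vector<uint64_t> raw;
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    std::string s = as<std::string>(reads[i]);
    std::vector<uint8_t> codes = encode_seq(s.c_str(), s.size());
    for_each_kmer(codes, k, [&](long, uint64_t fwd, uint64_t rev) {
      raw.push_back(std::min(fwd, rev));
    });
  }
  std::sort(raw.begin(), raw.end());
  for (size_t i = 0; i < raw.size();) {
    size_t j = i;
    while (j < raw.size() && raw[j] == raw[i]) ++j;
    g->keys.push_back(raw[i]);
    g->counts.push_back((uint32_t)(j - i));
    i = j;
  }
  XPtr<DBG> ptr(g, true);
  return ptr;
}

// [[Rcpp::export]]
List dbg_info_cpp(SEXP ptr_) {
  XPtr<DBG> ptr(ptr_);
  double total = 0;
  for (size_t i = 0; i < ptr->counts.size(); ++i) total += ptr->counts[i];
  return List::create(_["k"] = ptr->k,
                      _["n_kmers"] = (double) ptr->keys.size(),
                      _["total_multiplicity"] = total);
}

// Full edge table (canonical k-mer, multiplicity); intended for small graphs
// in tests and diagnostics.
// [[Rcpp::export]]
DataFrame dbg_edges_cpp(SEXP ptr_) {
  XPtr<DBG> ptr(ptr_);
  const size_t n = ptr->keys.size();
  CharacterVector kmer(n);
  IntegerVector count(n);
  for (size_t i = 0; i < n; ++i) {
    kmer[i] = decode_kmer(ptr->keys[i], ptr->k);
    count[i] = (int) ptr->counts[i];
  }
  return DataFrame::create(_["kmer"] = kmer, _["count"] = count,
                           _["stringsAsFactors"] = false);
}

struct PathRec {
  std::vector<long> kmer_idx;     // canonical indices along the walk
  std::string seq;                // oriented walk sequence
  bool dead_start = false, dead_end = false;
};

// Maximal non-branching walks covering every k-mer exactly once.
// Deterministic: seeds walks from canonical k-mers in ascending key order.
static std::vector<PathRec> dbg_paths(const DBG& g) {
  std::vector<PathRec> paths;
  const size_t n = g.keys.size();
  std::vector<char> visited(n, 0);
  for (size_t start = 0; start < n; ++start) {
    if (visited[start]) continue;
    visited[start] = 1;
    std::vector<std::pair<uint64_t, long> > fwd_ext, bwd_ext;
    // forward walk
    uint64_t f = g.keys[start];
    for (;;) {
      uint64_t nf;
      if (dbg_succ(g, f, &nf) != 1) break;
      uint64_t back;
      if (dbg_pred(g, nf, &back) != 1) break;
      const uint64_t canon = std::min(nf, revcomp_bits(nf, g.k));
      const long ci = dbg_find(g, canon);
      if (visited[ci]) break;
      visited[ci] = 1;
      fwd_ext.push_back(std::make_pair(nf, ci));
      f = nf;
    }
    // backward walk: extend the reverse complement forward
    uint64_t r = revcomp_bits(g.keys[start], g.k);
    for (;;) {
      uint64_t nr;
      if (dbg_succ(g, r, &nr) != 1) break;
      uint64_t back;
      if (dbg_pred(g, nr, &back) != 1) break;
      const uint64_t canon = std::min(nr, revcomp_bits(nr, g.k));
      const long ci = dbg_find(g, canon);
      if (visited[ci]) break;
      visited[ci] = 1;
      bwd_ext.push_back(std::make_pair(nr, ci));
      r = nr;
    }
    PathRec p;
    std::vector<uint64_t> oriented;
    for (size_t i = bwd_ext.size(); i-- > 0;) {
      oriented.push_back(revcomp_bits(bwd_ext[i].first, g.k));
      p.kmer_idx.push_back(bwd_ext[i].second);
    }
    oriented.push_back(g.keys[start]);
    p.kmer_idx.push_back((long) start);
    for (size_t i = 0; i < fwd_ext.size(); ++i) {
      oriented.push_back(fwd_ext[i].first);
      p.kmer_idx.push_back(fwd_ext[i].second);
    }
    p.seq = decode_kmer(oriented[0], g.k);
    for (size_t i = 1; i < oriented.size(); ++i)
      p.seq.push_back(CODE2BASE[oriented[i] & 3ULL]);
    uint64_t dummy;
    p.dead_start = dbg_pred(g, oriented.front(), &dummy) == 0;
    p.dead_end = dbg_succ(g, oriented.back(), &dummy) == 0;
    paths.push_back(p);
  }
  return paths;
}

// Tip, low-coverage and junction-relative cleaning, iterated to a fixpoint
// (hence idempotent). A tip is a walk dangling at exactly one end and
// shorter than tip_len_factor * k bases; isolated short walks are kept.
// Junction-relative cleaning drops an edge whose multiplicity is below
// junction_rel times its strongest sibling at a branch point: sequencing
// errors recur at high coverage (two reads hitting the same position with
// the same substitution pass any small absolute cutoff), and only a
// coverage-relative rule removes them without harming genuinely
// low-abundance replicons, whose branch-free edges have no dominant
// sibling.
// [[Rcpp::export]]
SEXP dbg_clean_cpp(SEXP ptr_, double tip_len_factor, int min_edge_cov,
                   double junction_rel) {
  XPtr<DBG> ptr(ptr_);
  DBG* g = new DBG();
  g->k = ptr->k;
  g->keys = ptr->keys;
  g->counts = ptr->counts;
  const double tip_max = tip_len_factor * (double) g->k;
  const uint64_t mask = kmask(g->k);
  for (int iter = 0; iter < 50; ++iter) {
    bool changed = false;
    // coverage filter
    std::vector<uint64_t> keys2;
    std::vector<uint32_t> counts2;
    for (size_t i = 0; i < g->keys.size(); ++i) {
      if ((int) g->counts[i] >= min_edge_cov) {
        keys2.push_back(g->keys[i]);
        counts2.push_back(g->counts[i]);
      } else changed = true;
    }
    g->keys.swap(keys2);
    g->counts.swap(counts2);
    // junction-relative filter (both the prefix junction and, via the
    // reverse complement, the suffix junction)
    if (junction_rel > 0) {
      std::vector<char> weak(g->keys.size(), 0);
      for (size_t i = 0; i < g->keys.size(); ++i) {
        for (int o = 0; o < 2; ++o) {
          const uint64_t f = o ? revcomp_bits(g->keys[i], g->k) : g->keys[i];
          const uint64_t base = ((f >> 2) << 2) & mask;
          uint32_t cmax = 0;
          int nsib = 0;
          for (uint64_t b = 0; b < 4; ++b) {
            const uint64_t sib = base | b;
            const long j = dbg_find(*g, std::min(sib, revcomp_bits(sib, g->k)));
            if (j >= 0) { ++nsib; cmax = std::max(cmax, g->counts[j]); }
          }
          if (nsib > 1 &&
              (double) g->counts[i] < junction_rel * (double) cmax)
            weak[i] = 1;
        }
      }
      std::vector<uint64_t> keysw;
      std::vector<uint32_t> countsw;
      for (size_t i = 0; i < g->keys.size(); ++i) {
        if (!weak[i]) { keysw.push_back(g->keys[i]); countsw.push_back(g->counts[i]); }
        else changed = true;
      }
      g->keys.swap(keysw);
      g->counts.swap(countsw);
    }
    // tip removal
    std::vector<PathRec> paths = dbg_paths(*g);
    std::vector<char> drop(g->keys.size(), 0);
    bool tips = false;
    for (size_t i = 0; i < paths.size(); ++i) {
      const PathRec& p = paths[i];
      const bool dangling = p.dead_start != p.dead_end;  // exactly one free end
      if (dangling && (double) p.seq.size() < tip_max) {
        for (size_t j = 0; j < p.kmer_idx.size(); ++j) drop[p.kmer_idx[j]] = 1;
        tips = true;
      }
    }
    if (tips) {
      changed = true;
      std::vector<uint64_t> keys3;
      std::vector<uint32_t> counts3;
      for (size_t i = 0; i < g->keys.size(); ++i) {
        if (!drop[i]) { keys3.push_back(g->keys[i]); counts3.push_back(g->counts[i]); }
      }
      g->keys.swap(keys3);
      g->counts.swap(counts3);
    }
    if (!changed) break;
  }
  XPtr<DBG> out(g, true);
  return out;
}

// [[Rcpp::export]]
List dbg_unitigs_cpp(SEXP ptr_, int min_len) {
  XPtr<DBG> ptr(ptr_);
  std::vector<PathRec> paths = dbg_paths(*ptr);
  std::vector<std::pair<std::string, double> > out;
  for (size_t i = 0; i < paths.size(); ++i) {
    const PathRec& p = paths[i];
    if ((int) p.seq.size() < min_len) continue;
    double cov = 0;
    for (size_t j = 0; j < p.kmer_idx.size(); ++j)
      cov += ptr->counts[p.kmer_idx[j]];
    cov /= (double) p.kmer_idx.size();
    // canonical orientation: lexicographically smaller of seq / revcomp
    std::string rc(p.seq.size(), 'N');
    for (size_t j = 0; j < p.seq.size(); ++j) {
      const char c = p.seq[p.seq.size() - 1 - j];
      rc[j] = (c == 'A') ? 'T' : (c == 'C') ? 'G' : (c == 'G') ? 'C'
            : (c == 'T') ? 'A' : 'N';
    }
    out.push_back(std::make_pair(std::min(p.seq, rc), cov));
  }
  std::sort(out.begin(), out.end());
  const size_t n = out.size();
  CharacterVector seq(n);
  NumericVector cov(n);
  for (size_t i = 0; i < n; ++i) { seq[i] = out[i].first; cov[i] = out[i].second; }
  return List::create(_["seq"] = seq, _["coverage"] = cov);
}
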