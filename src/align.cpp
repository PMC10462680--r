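#include "core.h"
using namespace Rcpp;

// [[Rcpp::export]]
CharacterVector revcomp_cpp(CharacterVector seqs) {
  CharacterVector out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    std::string r(s.size(), 'N');
    for (size_t j = 0; j < s.size(); ++j) {
      char c = s[s.size() - 1 - j];
      switch (c) {
        case 'A': r[j] = 'T'; break; case 'a': r[j] = 'T'; break;
        case 'C': r[j] = 'G'; break; case 'c': r[j] = 'G'; break;
        case 'G': r[j] = 'C'; break; case 'g': r[j] = 'C'; break;
        case 'T': r[j] = 'A'; break; case 't': r[j] = 'A'; break;
        case 'N': r[j] = 'N'; break; case 'n': r[j] = 'N'; break;
        default:
          stop("revcomp: invalid character '%s' at position %d",
               std::string(1, c).c_str(), (int)(s.size() - j));
      }
    }
    out[i] = r;
  }
  return out;
}

// [[Rcpp::export]]
SEXP build_kmer_index_cpp(CharacterVector names, CharacterVector seqs, int k) {
  if (k < 11 || k > 31 || k % 2 == 0)
    stop("k must be an odd integer in [11, 31]");
  KmerIndex* idx = new KmerIndex();
  idx->k = k;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    idx->names.push_back(as<std::string>(names[i]));
    idx->seqs.push_back(encode_seq(s.c_str(), s.size()));
    idx->total_len += s.size();
  }
  for (size_t ci = 0; ci < idx->seqs.size(); ++ci) {
    const std::vector<uint8_t>& codes = idx->seqs[ci];
    for_each_kmer(codes, k, [&](long pos, uint64_t fwd, uint64_t rev) {
      const uint64_t canon = std::min(fwd, rev);
      const uint64_t packed =
        ((uint64_t) ci << 34) | ((uint64_t) pos << 1) | (fwd <= rev ? 1ULL : 0ULL);
      idx->occ[canon].push_back(packed);
    });
  }
  XPtr<KmerIndex> ptr(idx, true);
  return ptr;
}

// [[Rcpp::export]]
List kmer_index_info_cpp(SEXP ptr_) {
  XPtr<KmerIndex> ptr(ptr_);
  return List::create(_["k"] = ptr->k,
                      _["n_contigs"] = (double) ptr->names.size(),
                      _["n_kmers"] = (double) ptr->occ.size(),
                      _["total_len"] = (double) ptr->total_len);
}

// Occurrence lookup (used by tests and diagnostics, not on the hot path).
// [[Rcpp::export]]
DataFrame kmer_lookup_cpp(SEXP ptr_, CharacterVector kmers) {
  XPtr<KmerIndex> ptr(ptr_);
  std::vector<std::string> q_out, contig_out;
  std::vector<double> pos_out;
  std::vector<int> fwd_out;
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    std::string s = as<std::string>(kmers[i]);
    if ((int) s.size() != ptr->k) stop("kmer length does not match index k");
    std::vector<uint8_t> codes = encode_seq(s.c_str(), s.size());
    bool valid = true;
    uint64_t fwd = 0;
    for (int j = 0; j < ptr->k; ++j) {
      if (codes[j] > 3) { valid = false; break; }
      fwd = (fwd << 2) | codes[j];
    }
    if (!valid) continue;
    const uint64_t canon = std::min(fwd, revcomp_bits(fwd, ptr->k));
    std::unordered_map<uint64_t, std::vector<uint64_t> >::const_iterator it =
      ptr->occ.find(canon);
    if (it == ptr->occ.end()) continue;
    for (size_t j = 0; j < it->second.size(); ++j) {
      const uint64_t p = it->second[j];
      q_out.push_back(s);
      contig_out.push_back(ptr->names[p >> 34]);
      pos_out.push_back((double)((p >> 1) & 0x1FFFFFFFFULL));
      fwd_out.push_back((int)(p & 1ULL));
    }
  }
  return DataFrame::create(_["kmer"] = q_out, _["contig"] = contig_out,
                           _["pos"] = pos_out, _["fwd_is_canonical"] = fwd_out,
                           _["stringsAsFactors"] = false);
}

// ---------------------------------------------------------------------------
// Seed collection shared by the read mapper and the HSP finder
// ---------------------------------------------------------------------------
struct Seed {
  uint32_t subject;
  uint8_t strand;   // 0 = +, 1 = -
  long diag;        // subject_pos - oriented_query_pos
  long qpos;        // position in the oriented query
  long spos;
};

static void collect_seeds(const KmerIndex& idx, const std::vector<uint8_t>& q,
                          std::vector<Seed>& seeds, size_t max_occ_per_kmer) {
  const int k = idx.k;
  const long L = (long) q.size();
  for_each_kmer(q, k, [&](long i, uint64_t fwd, uint64_t rev) {
    const uint64_t canon = std::min(fwd, rev);
    const bool read_fwd_canon = (fwd <= rev);
    std::unordered_map<uint64_t, std::vector<uint64_t> >::const_iterator it =
      idx.occ.find(canon);
    if (it == idx.occ.end()) return;
    const size_t nocc = std::min(it->second.size(), max_occ_per_kmer);
    for (size_t j = 0; j < nocc; ++j) {
      const uint64_t packed = it->second[j];
      const uint32_t ci = (uint32_t)(packed >> 34);
      const long p = (long)((packed >> 1) & 0x1FFFFFFFFULL);
      const bool contig_fwd_canon = (packed & 1ULL) != 0;
      Seed sd;
      sd.subject = ci;
      if (read_fwd_canon == contig_fwd_canon) {       // same strand
        sd.strand = 0; sd.qpos = i;
      } else {                                        // query maps reversed
        sd.strand = 1; sd.qpos = L - k - i;
      }
      sd.diag = p - sd.qpos;
      sd.spos = p;
      seeds.push_back(sd);
    }
  });
}

struct Candidate {
  uint32_t subject;
  uint8_t strand;
  long diag;        // representative diagonal (most-seeded)
  long diag_min, diag_max;
  long q_min, q_max;  // oriented query extent of seed starts
  long s_min;
  int nseeds;
};

// Longest alignment window whose identity is >= win_id: longest interval of
// columns with nonnegative sum of (match*scale - win_id*scale), found with a
// prefix-sum monotonic stack in O(columns).
struct Win { long len = 0; long matches = 0; long a = 0, b = 0; };

static Win longest_window(const AlnCols& c, double win_id) {
  const long n = (long) c.is_match.size();
  Win best;
  if (n == 0) return best;
  const long long scale = 1000000LL;
  const long long p = (long long) llround(win_id * (double) scale);
  std::vector<long long> P(n + 1, 0), M(n + 1, 0);
  for (long i = 0; i < n; ++i) {
    P[i + 1] = P[i] + ((c.is_match[i] ? scale : 0) - p);
    M[i + 1] = M[i] + (c.is_match[i] ? 1 : 0);
  }
  std::vector<long> st;
  st.push_back(0);
  for (long i = 1; i <= n; ++i) if (P[i] < P[st.back()]) st.push_back(i);
  for (long r = n; r >= 1; --r) {
    while (!st.empty() && P[st.back()] <= P[r]) {
      const long l = st.back(); st.pop_back();
      if (r - l > best.len) {
        best.len = r - l; best.a = l; best.b = r;
        best.matches = M[r] - M[l];
      }
    }
    if (st.empty()) break;
  }
  return best;
}

// coordinate extent and score of a column window [a, b)
struct WinStats {
  long q_beg = -1, q_end = -1, s_beg = -1, s_end = -1;
  int score = 0;
};

static WinStats window_stats(const AlnCols& c, long a, long b,
                             int match, int mismatch, int gap) {
  WinStats w;
  for (long i = a; i < b; ++i) {
    const long qp = c.qpos[i], sp = c.spos[i];
    if (qp >= 0) { if (w.q_beg < 0) w.q_beg = qp; w.q_end = qp + 1; }
    if (sp >= 0) { if (w.s_beg < 0) w.s_beg = sp; w.s_end = sp + 1; }
    if (qp >= 0 && sp >= 0) w.score += c.is_match[i] ? match : mismatch;
    else w.score -= gap;
  }
  return w;
}

// ---------------------------------------------------------------------------
// Read mapper: group seeds into banded candidates, align each, keep the best
// passing placement. Deterministic tie-break: score desc, contig name asc,
// subject start asc.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
DataFrame map_reads_cpp(SEXP ptr_, CharacterVector ids, CharacterVector seqs,
                        double min_identity, double min_aligned_frac,
                        int band, int match, int mismatch, int gap,
                        int max_candidates) {
  XPtr<KmerIndex> ptr(ptr_);
  const KmerIndex& idx = *ptr;
  const int k = idx.k;
  const R_xlen_t n = seqs.size();

  LogicalVector mapped(n), too_short(n);
  CharacterVector contig(n), strand(n);
  NumericVector s_start(n, NA_REAL), s_end(n, NA_REAL);
  NumericVector identity(n, NA_REAL), frac(n, NA_REAL), score(n, NA_REAL);
  IntegerVector read_len(n);

  std::vector<Seed> seeds;
  for (R_xlen_t ri = 0; ri < n; ++ri) {
    std::string s = as<std::string>(seqs[ri]);
    const long L = (long) s.size();
    read_len[ri] = (int) L;
    mapped[ri] = false;
    contig[ri] = NA_STRING; strand[ri] = NA_STRING;
    if (L < k) { too_short[ri] = true; continue; }
    too_short[ri] = false;

    std::vector<uint8_t> qf = encode_seq(s.c_str(), s.size());
    std::vector<uint8_t> qr = revcomp_codes(qf);

    seeds.clear();
    collect_seeds(idx, qf, seeds, 64);
    if (seeds.empty()) continue;
    std::sort(seeds.begin(), seeds.end(), [](const Seed& a, const Seed& b) {
      if (a.subject != b.subject) return a.subject < b.subject;
      if (a.strand != b.strand) return a.strand < b.strand;
      if (a.diag != b.diag) return a.diag < b.diag;
      return a.qpos < b.qpos;
    });

    // merge seeds on nearby diagonals into candidates
    std::vector<Candidate> cands;
    for (size_t i = 0; i < seeds.size(); ++i) {
      const Seed& sd = seeds[i];
      if (!cands.empty()) {
        Candidate& c = cands.back();
        if (c.subject == sd.subject && c.strand == sd.strand &&
            sd.diag - c.diag_max <= (long) band) {
          c.diag_max = sd.diag;
          c.q_min = std::min(c.q_min, sd.qpos);
          c.q_max = std::max(c.q_max, sd.qpos);
          c.s_min = std::min(c.s_min, sd.spos);
          c.nseeds++;
          continue;
        }
      }
      Candidate c;
      c.subject = sd.subject; c.strand = sd.strand;
      c.diag = sd.diag; c.diag_min = sd.diag; c.diag_max = sd.diag;
      c.q_min = sd.qpos; c.q_max = sd.qpos; c.s_min = sd.spos;
      c.nseeds = 1;
      cands.push_back(c);
    }
    std::sort(cands.begin(), cands.end(), [&](const Candidate& a, const Candidate& b) {
      if (a.nseeds != b.nseeds) return a.nseeds > b.nseeds;
      const int cmp = idx.names[a.subject].compare(idx.names[b.subject]);
      if (cmp != 0) return cmp < 0;
      if (a.strand != b.strand) return a.strand < b.strand;
      return a.diag_min < b.diag_min;
    });
    if ((int) cands.size() > max_candidates) cands.resize(max_candidates);

    // A candidate qualifies when its alignment contains a window with
    // identity >= min_identity spanning >= min_aligned_frac of the read
    // ("some alignment qualifies" semantics; a co-optimal traceback with
    // trailing near-neutral columns must not flip the decision).
    bool have_best = false;
    int best_score = 0;
    long best_sb = 0, best_se = 0;
    double best_id = 0, best_fr = 0;
    uint32_t best_subject = 0; uint8_t best_strand = 0;
    for (size_t c = 0; c < cands.size(); ++c) {
      const Candidate& cd = cands[c];
      const std::vector<uint8_t>& q = (cd.strand == 0) ? qf : qr;
      const std::vector<uint8_t>& sub = idx.seqs[cd.subject];
      const long dc = (cd.diag_min + cd.diag_max) / 2;
      const int be = band + (int)((cd.diag_max - cd.diag_min) / 2 + 1);
      AlnCols cols;
      Aln a = banded_local(q.data(), 0, L, sub.data(), (long) sub.size(),
                           dc, be, match, mismatch, gap, &cols);
      if (!a.valid || a.columns == 0) continue;
      const Win w = longest_window(cols, min_identity - 1e-12);
      if (w.len == 0) continue;
      const WinStats ws = window_stats(cols, w.a, w.b, match, mismatch, gap);
      const double id = (double) w.matches / (double) w.len;
      const double fr = (double)(ws.q_end - ws.q_beg) / (double) L;
      if (fr + 1e-12 < min_aligned_frac) continue;
      bool better = false;
      if (!have_best) better = true;
      else if (ws.score != best_score) better = ws.score > best_score;
      else {
        const int cmp = idx.names[cd.subject].compare(idx.names[best_subject]);
        if (cmp != 0) better = cmp < 0;
        else better = ws.s_beg < best_sb;
      }
      if (better) {
        have_best = true;
        best_score = ws.score; best_sb = ws.s_beg; best_se = ws.s_end;
        best_id = id; best_fr = fr;
        best_subject = cd.subject; best_strand = cd.strand;
      }
    }
    if (have_best) {
      mapped[ri] = true;
      contig[ri] = idx.names[best_subject];
      strand[ri] = (best_strand == 0) ? "+" : "-";
      s_start[ri] = (double) best_sb;
      s_end[ri] = (double) best_se;
      identity[ri] = best_id;
      frac[ri] = best_fr;
      score[ri] = (double) best_score;
    }
  }
  return DataFrame::create(
    _["id"] = ids, _["mapped"] = mapped, _["too_short"] = too_short,
    _["contig"] = contig, _["s_start"] = s_start, _["s_end"] = s_end,
    _["strand"] = strand, _["identity"] = identity,
    _["aligned_frac"] = frac, _["score"] = score, _["read_len"] = read_len,
    _["stringsAsFactors"] = false);
}

// ---------------------------------------------------------------------------
// BLAST-like HSP discovery: seeds chained along diagonals, each chain
// extended by a banded local alignment. Subject coordinates are always on
// the subject forward strand; query coordinates on the query forward strand.
// ---------------------------------------------------------------------------
struct HspRec {
  std::string qid, sid;
  uint8_t strand;
  long q_start, q_end, s_start, s_end;
  int length, matches, score;
  long wlen, wmatches, wq_start, wq_end, ws_start, ws_end;
};

// [[Rcpp::export]]
DataFrame find_hsps_cpp(CharacterVector qids, CharacterVector qseqs, SEXP ptr_,
                        int band, int match, int mismatch, int gap,
                        int min_hsp_len, int max_chain_gap, int margin,
                        double win_id) {
  XPtr<KmerIndex> ptr(ptr_);
  const KmerIndex& idx = *ptr;
  const int k = idx.k;
  std::vector<HspRec> all;

  for (R_xlen_t qi = 0; qi < qseqs.size(); ++qi) {
    std::string s = as<std::string>(qseqs[qi]);
    const long L = (long) s.size();
    if (L < k) continue;
    std::vector<uint8_t> qf = encode_seq(s.c_str(), s.size());
    std::vector<uint8_t> qr = revcomp_codes(qf);
    std::vector<Seed> seeds;
    collect_seeds(idx, qf, seeds, 64);
    if (seeds.empty()) continue;
    // cluster per (subject, strand) in query order, tolerating diagonal drift
    std::sort(seeds.begin(), seeds.end(), [](const Seed& a, const Seed& b) {
      if (a.subject != b.subject) return a.subject < b.subject;
      if (a.strand != b.strand) return a.strand < b.strand;
      if (a.qpos != b.qpos) return a.qpos < b.qpos;
      return a.diag < b.diag;
    });
    struct Cluster { uint32_t subject; uint8_t strand;
                     long dmin, dmax, qmin, qmax; };
    std::vector<Cluster> clusters;
    for (size_t i = 0; i < seeds.size(); ++i) {
      const Seed& sd = seeds[i];
      bool joined = false;
      if (!clusters.empty()) {
        Cluster& c = clusters.back();
        if (c.subject == sd.subject && c.strand == sd.strand &&
            sd.qpos - c.qmax <= (long) max_chain_gap &&
            sd.diag >= c.dmin - band && sd.diag <= c.dmax + band) {
          c.dmin = std::min(c.dmin, sd.diag);
          c.dmax = std::max(c.dmax, sd.diag);
          c.qmax = std::max(c.qmax, sd.qpos);
          joined = true;
        }
      }
      if (!joined) {
        Cluster c;
        c.subject = sd.subject; c.strand = sd.strand;
        c.dmin = sd.diag; c.dmax = sd.diag;
        c.qmin = sd.qpos; c.qmax = sd.qpos;
        clusters.push_back(c);
      }
    }
    std::vector<HspRec> here;
    for (size_t c = 0; c < clusters.size(); ++c) {
      const Cluster& cl = clusters[c];
      const std::vector<uint8_t>& q = (cl.strand == 0) ? qf : qr;
      const std::vector<uint8_t>& sub = idx.seqs[cl.subject];
      const long q0 = std::max(0L, cl.qmin - (long) margin);
      const long q1 = std::min(L, cl.qmax + (long) k + (long) margin);
      const long dc = (cl.dmin + cl.dmax) / 2;
      const int be = band + (int)((cl.dmax - cl.dmin) / 2 + 1);
      AlnCols cols;
      Aln a = banded_local(q.data(), q0, q1, sub.data(), (long) sub.size(),
                           dc, be, match, mismatch, gap, &cols);
      if (!a.valid || a.columns < min_hsp_len) continue;
      HspRec h;
      h.qid = as<std::string>(qids[qi]);
      h.sid = idx.names[cl.subject];
      h.strand = cl.strand;
      if (cl.strand == 0) { h.q_start = a.q_beg; h.q_end = a.q_end; }
      else { h.q_start = L - a.q_end; h.q_end = L - a.q_beg; }
      h.s_start = a.s_beg; h.s_end = a.s_end;
      h.length = a.columns; h.matches = a.matches; h.score = a.score;
      const Win w = longest_window(cols, win_id);
      h.wlen = w.len; h.wmatches = w.matches;
      h.wq_start = 0; h.wq_end = 0; h.ws_start = 0; h.ws_end = 0;
      if (w.len > 0) {
        long qmn = -1, qmx = -1, smn = -1, smx = -1;
        for (long ci2 = w.a; ci2 < w.b; ++ci2) {
          const long qp = cols.qpos[ci2], sp = cols.spos[ci2];
          if (qp >= 0) { if (qmn < 0) qmn = qp; qmx = qp; }
          if (sp >= 0) { if (smn < 0) smn = sp; smx = sp; }
        }
        if (cl.strand == 0) { h.wq_start = qmn; h.wq_end = qmx + 1; }
        else { h.wq_start = L - (qmx + 1); h.wq_end = L - qmn; }
        h.ws_start = smn; h.ws_end = smx + 1;
      }
      here.push_back(h);
    }
    // dedup: drop HSPs mostly overlapping a higher-scoring one on the same
    // (subject, strand)
    std::sort(here.begin(), here.end(), [](const HspRec& a, const HspRec& b) {
      if (a.score != b.score) return a.score > b.score;
      if (a.sid != b.sid) return a.sid < b.sid;
      if (a.s_start != b.s_start) return a.s_start < b.s_start;
      return a.strand < b.strand;
    });
    std::vector<HspRec> kept;
    for (size_t i = 0; i < here.size(); ++i) {
      bool dup = false;
      for (size_t j = 0; j < kept.size(); ++j) {
        const HspRec& kh = kept[j];
        if (kh.sid != here[i].sid || kh.strand != here[i].strand) continue;
        const long so = std::min(kh.s_end, here[i].s_end) -
                        std::max(kh.s_start, here[i].s_start);
        const long qo = std::min(kh.q_end, here[i].q_end) -
                        std::max(kh.q_start, here[i].q_start);
        const long sspan = std::min(kh.s_end - kh.s_start,
                                    here[i].s_end - here[i].s_start);
        const long qspan = std::min(kh.q_end - kh.q_start,
                                    here[i].q_end - here[i].q_start);
        if (sspan > 0 && qspan > 0 &&
            so * 2 > sspan && qo * 2 > qspan) { dup = true; break; }
      }
      if (!dup) kept.push_back(here[i]);
    }
    for (size_t i = 0; i < kept.size(); ++i) all.push_back(kept[i]);
  }

  const size_t m = all.size();
  CharacterVector qid(m), sid(m), strand(m);
  NumericVector q_start(m), q_end(m), s_start(m), s_end(m);
  IntegerVector length(m), matches(m), score(m);
  NumericVector identity(m);
  NumericVector win_len(m), win_matches(m), win_identity(m);
  NumericVector win_q_start(m), win_q_end(m), win_s_start(m), win_s_end(m);
  for (size_t i = 0; i < m; ++i) {
    qid[i] = all[i].qid; sid[i] = all[i].sid;
    strand[i] = all[i].strand == 0 ? "+" : "-";
    q_start[i] = (double) all[i].q_start; q_end[i] = (double) all[i].q_end;
    s_start[i] = (double) all[i].s_start; s_end[i] = (double) all[i].s_end;
    length[i] = all[i].length; matches[i] = all[i].matches;
    score[i] = all[i].score;
    identity[i] = (double) all[i].matches / (double) all[i].length;
    win_len[i] = (double) all[i].wlen;
    win_matches[i] = (double) all[i].wmatches;
    win_identity[i] = all[i].wlen > 0 ?
      (double) all[i].wmatches / (double) all[i].wlen : NA_REAL;
    win_q_start[i] = (double) all[i].wq_start;
    win_q_end[i] = (double) all[i].wq_end;
    win_s_start[i] = (double) all[i].ws_start;
    win_s_end[i] = (double) all[i].ws_end;
  }
  return DataFrame::create(
    _["qid"] = qid, _["sid"] = sid, _["strand"] = strand,
    _["q_start"] = q_start, _["q_end"] = q_end,
    _["s_start"] = s_start, _["s_end"] = s_end,
    _["length"] = length, _["matches"] = matches,
    _["identity"] = identity, _["score"] = score,
    _["win_len"] = win_len, _["win_matches"] = win_matches,
    _["win_identity"] = win_identity,
    _["win_q_start"] = win_q_start, _["win_q_end"] = win_q_end,
    _["win_s_start"] = win_s_start, _["win_s_end"] = win_s_end,
    _["stringsAsFactors"] = false);
}
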