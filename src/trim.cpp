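#include <Rcpp.h>
#include <string>
using namespace Rcpp;

// 3' sliding-window mean-quality trimming over Phred+33 quality strings.
// The trailing window of `window` bases is inspected; while its mean quality
// is below min_mean_q the whole window is cut and the next trailing window
// inspected. Reads ending shorter than min_len are discarded. Surviving
// bases are never altered, so output is always a prefix of the input.
// [[Rcpp::export]]
List trim_reads_cpp(CharacterVector seqs, CharacterVector quals,
                    int window, int min_mean_q, int min_len) {
  const R_xlen_t n = seqs.size();
  if (quals.size() != n)
    stop("seqs and quals must have equal length");
  CharacterVector seq_out(n), qual_out(n);
  LogicalVector keep(n);
  IntegerVector len_out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    std::string q = as<std::string>(quals[i]);
    if (s.size() != q.size())
      stop("read %d: sequence and quality lengths differ (%d vs %d)",
           (int)(i + 1), (int) s.size(), (int) q.size());
    long len = (long) s.size();
    while (len >= window) {
      long sum = 0;
      for (long j = len - window; j < len; ++j) sum += (long) q[j] - 33;
      if ((double) sum / (double) window >= (double) min_mean_q) break;
      len -= window;
    }
    if (len < min_len) {
      keep[i] = false;
      seq_out[i] = NA_STRING; qual_out[i] = NA_STRING; len_out[i] = 0;
    } else {
      keep[i] = true;
      seq_out[i] = s.substr(0, len);
      qual_out[i] = q.substr(0, len);
      len_out[i] = (int) len;
    }
  }
  return List::create(_["seq"] = seq_out, _["qual"] = qual_out,
                      _["keep"] = keep, _["length"] = len_out);
}

// depth[i] = number of half-open intervals [start, end) containing i.
// [[Rcpp::export]]
IntegerVector interval_depth_cpp(int contig_len, NumericVector starts,
                                 NumericVector ends) {
  IntegerVector depth(contig_len, 0);
  std::vector<int> delta(contig_len + 1, 0);
  for (R_xlen_t i = 0; i < starts.size(); ++i) {
    const long a = (long) starts[i], b = (long) ends[i];
    if (a < 0 || b > contig_len || a >= b)
      stop("interval [%d, %d) out of bounds for contig of length %d",
           (int) a, (int) b, contig_len);
    delta[a] += 1; delta[b] -= 1;
  }
  int run = 0;
  for (int i = 0; i < contig_len; ++i) { run += delta[i]; depth[i] = run; }
  return depth;
}
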