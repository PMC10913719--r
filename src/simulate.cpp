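// Read-level simulation helpers: substitution errors, per-base quality
// strings, and sliding-window quality trimming. All randomness goes through
// R's RNG so set.seed() in R governs reproducibility.
#include <Rcpp.h>
#include <string>
using namespace Rcpp;

static const char BASES[4] = {'A', 'C', 'G', 'T'};

// Independent per-base substitutions at error_rate; never substitutes a base
// for itself (draws one of the 3 alternatives).
// [[Rcpp::export]]
CharacterVector cpp_add_errors(CharacterVector seqs, double error_rate) {
  RNGScope scope;
  R_xlen_t n = seqs.size();
  CharacterVector out(n);
  std::string buf;
  for (R_xlen_t i = 0; i < n; ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    int len = (int)LENGTH(STRING_ELT(seqs, i));
    int nerr = (int)R::rbinom((double)len, error_rate);
    if (nerr == 0) { out[i] = STRING_ELT(seqs, i); continue; }
    buf.assign(s, len);
    for (int e = 0; e < nerr; ++e) {
      int pos = (int)(R::unif_rand() * len);
      if (pos >= len) pos = len - 1;
      char cur = buf[pos];
      int alt = (int)(R::unif_rand() * 3);
      for (int b = 0; b < 4; ++b) {
        if (BASES[b] == cur) continue;
        if (alt-- == 0) { buf[pos] = BASES[b]; break; }
      }
    }
    out[i] = buf;
  }
  return out;
}

// Phred+33 quality strings: base quality ~ round(N(hi_mean, hi_sd)) clipped to
// [lo_min, 40]; a tail_frac share of reads get a low-quality 3' tail starting
// uniformly in the second half of the read, with qualities U{2..14} (< Q20).
// [[Rcpp::export]]
CharacterVector cpp_sim_quals(IntegerVector lens, double tail_frac,
                              double hi_mean, double hi_sd) {
  RNGScope scope;
  R_xlen_t n = lens.size();
  CharacterVector out(n);
  std::string buf;
  for (R_xlen_t i = 0; i < n; ++i) {
    int len = lens[i];
    buf.resize(len);
    int tail_start = len;  // no tail
    if (R::unif_rand() < tail_frac) {
      tail_start = len / 2 + (int)(R::unif_rand() * (len - len / 2));
      if (tail_start >= len) tail_start = len - 1;
    }
    for (int j = 0; j < len; ++j) {
      int q;
      if (j >= tail_start) {
        q = 2 + (int)(R::unif_rand() * 13);  // 2..14
        if (q > 14) q = 14;
      } else {
        q = (int)(R::rnorm(hi_mean, hi_sd) + 0.5);
        if (q < 20) q = 20;
        if (q > 40) q = 40;
      }
      buf[j] = (char)(q + 33);
    }
    out[i] = buf;
  }
  return out;
}

// Sliding-window quality trim: scan windows left to right; at the first
// window whose mean quality < min_mean_q, truncate at that window's start.
// Returns the kept length per read (may equal the read length: no trim).
// [[Rcpp::export]]
IntegerVector cpp_window_trim(CharacterVector quals, int window,
                              double min_mean_q) {
  R_xlen_t n = quals.size();
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const char* q = CHAR(STRING_ELT(quals, i));
    int len = (int)LENGTH(STRING_ELT(quals, i));
    int keep = len;
    if (len >= window) {
      int sum = 0;
      for (int j = 0; j < window; ++j) sum += q[j] - 33;
      for (int start = 0;; ++start) {
        if ((double)sum / window < min_mean_q) { keep = start; break; }
        if (start + window >= len) break;
        sum += (q[start + window] - 33) - (q[start] - 33);
      }
    }
    out[i] = keep;
  }
  return out;
}
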