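// k-mer machinery shared by the classifier, the depletion filter, the marker
// profiler and the nucleotide-tier functional search. k <= 31 so a k-mer fits
// in 2 bits/base within a uint64_t; canonical form = min(kmer, revcomp).
#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <cstdint>
using namespace Rcpp;

static inline int base2bits(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

// Enumerate canonical k-mers of seq; invalid (non-ACGT) windows are skipped.
// Calls fun(canonical_kmer, position) for each valid window (0-based pos).
template <typename F>
static void for_each_canonical(const char* s, int n, int k, F fun) {
  if (n < k) return;
  uint64_t fwd = 0, rev = 0;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  int run = 0;  // number of consecutive valid bases ending at i
  for (int i = 0; i < n; ++i) {
    int b = base2bits(s[i]);
    if (b < 0) { run = 0; fwd = rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)b) & mask;
    rev = (rev >> 2) | ((uint64_t)(3 - b) << (2 * (k - 1)));
    if (++run >= k) {
      uint64_t canon = fwd < rev ? fwd : rev;
      fun(canon, i - k + 1);
    }
  }
}

static inline int count_valid_kmers(const char* s, int n, int k) {
  int cnt = 0;
  for_each_canonical(s, n, k, [&](uint64_t, int) { ++cnt; });
  return cnt;
}

// ---------------------------------------------------------------------------
// Taxon-labelled k-mer index (LCA of all source genomes containing the k-mer)
// ---------------------------------------------------------------------------

struct KmerIndex {
  int k;
  std::unordered_map<uint64_t, int> map;  // canonical k-mer -> node (1-based)
};

// parent: 1-based parent index per node, 0 for the root; depth: root = 0.
static int lca_pair(int a, int b, const int* parent, const int* depth) {
  while (depth[a - 1] > depth[b - 1]) a = parent[a - 1];
  while (depth[b - 1] > depth[a - 1]) b = parent[b - 1];
  while (a != b) { a = parent[a - 1]; b = parent[b - 1]; }
  return a;
}

// [[Rcpp::export]]
SEXP kidx_build(CharacterVector seqs, IntegerVector taxon,
                IntegerVector parent, IntegerVector depth, int k) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  XPtr<KmerIndex> xp(new KmerIndex, true);
  xp->k = k;
  const int* par = INTEGER(parent);
  const int* dep = INTEGER(depth);
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    int n = (int)LENGTH(STRING_ELT(seqs, i));
    int tx = taxon[i];
    for_each_canonical(s, n, k, [&](uint64_t km, int) {
      auto it = xp->map.find(km);
      if (it == xp->map.end()) xp->map.emplace(km, tx);
      else if (it->second != tx) it->second = lca_pair(it->second, tx, par, dep);
    });
  }
  return xp;
}

// [[Rcpp::export]]
double kidx_size(SEXP xp_) {
  XPtr<KmerIndex> xp(xp_);
  return (double)xp->map.size();
}

// Lookup explicit k-mer strings (0 = absent); used by tests.
// [[Rcpp::export]]
IntegerVector kidx_lookup(SEXP xp_, CharacterVector kmers) {
  XPtr<KmerIndex> xp(xp_);
  IntegerVector out(kmers.size(), 0);
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    const char* s = CHAR(STRING_ELT(kmers, i));
    int n = (int)LENGTH(STRING_ELT(kmers, i));
    if (n != xp->k) stop("k-mer length must equal index k");
    for_each_canonical(s, n, xp->k, [&](uint64_t km, int) {
      auto it = xp->map.find(km);
      if (it != xp->map.end()) out[i] = it->second;
    });
  }
  return out;
}

// Classify reads: per read collect per-node hit counts, pick the leaf-ward
// node maximising the summed hits along its root-to-node path (tie: deepest,
// then lowest node index), then ascend while the rooted-clade confidence is
// below the threshold. Returns node index (0 = unclassified) and confidence.
// [[Rcpp::export]]
List kidx_classify(SEXP xp_, CharacterVector reads, IntegerVector parent,
                   IntegerVector depth, double threshold) {
  XPtr<KmerIndex> xp(xp_);
  const int k = xp->k;
  const int* par = INTEGER(parent);
  const int* dep = INTEGER(depth);
  R_xlen_t nr = reads.size();
  IntegerVector out_tax(nr, 0);
  NumericVector out_conf(nr, 0.0);
  std::unordered_map<int, int> hits, clade;
  for (R_xlen_t i = 0; i < nr; ++i) {
    const char* s = CHAR(STRING_ELT(reads, i));
    int n = (int)LENGTH(STRING_ELT(reads, i));
    int valid = 0;
    hits.clear();
    for_each_canonical(s, n, k, [&](uint64_t km, int) {
      ++valid;
      auto it = xp->map.find(km);
      if (it != xp->map.end()) ++hits[it->second];
    });
    if (valid == 0 || hits.empty()) continue;
    // rooted-clade counts: propagate each hit to all its ancestors
    clade.clear();
    for (auto& h : hits) {
      int node = h.first;
      while (node != 0) { clade[node] += h.second; node = par[node - 1]; }
    }
    // candidate: hit node maximising path score (sum of hits on root..node)
    int best = 0, best_score = -1, best_depth = -1;
    for (auto& h : hits) {
      int node = h.first, score = 0;
      int a = node;
      while (a != 0) {
        auto it = hits.find(a);
        if (it != hits.end()) score += it->second;
        a = par[a - 1];
      }
      int d = dep[node - 1];
      if (score > best_score ||
          (score == best_score && (d > best_depth ||
                                   (d == best_depth && node < best)))) {
        best = node; best_score = score; best_depth = d;
      }
    }
    // ascend until the clade confidence meets the threshold
    int node = best;
    double conf = 0.0;
    while (node != 0) {
      conf = (double)clade[node] / (double)valid;
      if (conf >= threshold) break;
      node = par[node - 1];
    }
    if (node != 0) { out_tax[i] = node; out_conf[i] = conf; }
  }
  return List::create(_["taxon"] = out_tax, _["confidence"] = out_conf);
}

// ---------------------------------------------------------------------------
// Plain k-mer set (reference depletion)
// ---------------------------------------------------------------------------

struct KmerSet {
  int k;
  std::unordered_set<uint64_t> set;
};

// [[Rcpp::export]]
SEXP kset_build(CharacterVector seqs, int k) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  XPtr<KmerSet> xp(new KmerSet, true);
  xp->k = k;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    int n = (int)LENGTH(STRING_ELT(seqs, i));
    for_each_canonical(s, n, k, [&](uint64_t km, int) { xp->set.insert(km); });
  }
  return xp;
}

// [[Rcpp::export]]
double kset_size(SEXP xp_) {
  XPtr<KmerSet> xp(xp_);
  return (double)xp->set.size();
}

// Fraction of each read's valid k-mers present in the set (0 if no valid kmer)
// [[Rcpp::export]]
NumericVector kset_fraction(SEXP xp_, CharacterVector reads) {
  XPtr<KmerSet> xp(xp_);
  const int k = xp->k;
  R_xlen_t nr = reads.size();
  NumericVector out(nr, 0.0);
  for (R_xlen_t i = 0; i < nr; ++i) {
    const char* s = CHAR(STRING_ELT(reads, i));
    int n = (int)LENGTH(STRING_ELT(reads, i));
    int valid = 0, hit = 0;
    for_each_canonical(s, n, k, [&](uint64_t km, int) {
      ++valid;
      if (xp->set.count(km)) ++hit;
    });
    if (valid > 0) out[i] = (double)hit / (double)valid;
  }
  return out;
}

// ---------------------------------------------------------------------------
// k-mer -> sequence-id multimap (marker hits; gene assignment with positions)
// ---------------------------------------------------------------------------

struct KmerMap {
  int k;
  // canonical k-mer -> list of (seq index 1-based, 0-based position)
  std::unordered_map<uint64_t, std::vector<std::pair<int, int>>> map;
};

// [[Rcpp::export]]
SEXP kmap_build(CharacterVector seqs, int k) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  XPtr<KmerMap> xp(new KmerMap, true);
  xp->k = k;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    int n = (int)LENGTH(STRING_ELT(seqs, i));
    for_each_canonical(s, n, k, [&](uint64_t km, int pos) {
      auto& v = xp->map[km];
      if (v.empty() || v.back().first != (int)(i + 1))
        v.emplace_back((int)(i + 1), pos);
    });
  }
  return xp;
}

// Number of reads whose shared-k-mer fraction with each target sequence is
// >= min_frac (a read may hit more than one target only if min_frac <= 0.5).
// [[Rcpp::export]]
IntegerVector kmap_hit_counts(SEXP xp_, CharacterVector reads, int n_targets,
                              double min_frac) {
  XPtr<KmerMap> xp(xp_);
  const int k = xp->k;
  IntegerVector out(n_targets, 0);
  std::unordered_map<int, int> cnt;
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    const char* s = CHAR(STRING_ELT(reads, i));
    int n = (int)LENGTH(STRING_ELT(reads, i));
    int valid = 0;
    cnt.clear();
    for_each_canonical(s, n, k, [&](uint64_t km, int) {
      ++valid;
      auto it = xp->map.find(km);
      if (it != xp->map.end())
        for (auto& pr : it->second) ++cnt[pr.first];
    });
    if (valid == 0) continue;
    for (auto& c : cnt)
      if ((double)c.second / (double)valid >= min_frac) ++out[c.first - 1];
  }
  return out;
}

// Best-target assignment: target with most shared k-mers, subject to
// fraction >= min_frac; ties broken by smaller tie_rank (1-based per target).
// Also returns the modal alignment start (1-based on the target; 0 if none).
// [[Rcpp::export]]
List kmap_assign(SEXP xp_, CharacterVector reads, int n_targets,
                 double min_frac, IntegerVector tie_rank) {
  XPtr<KmerMap> xp(xp_);
  const int k = xp->k;
  R_xlen_t nr = reads.size();
  IntegerVector out_tgt(nr, 0), out_start(nr, 0);
  std::unordered_map<int, int> cnt;
  std::unordered_map<long long, int> offs;  // (target, offset) -> votes
  for (R_xlen_t i = 0; i < nr; ++i) {
    const char* s = CHAR(STRING_ELT(reads, i));
    int n = (int)LENGTH(STRING_ELT(reads, i));
    int valid = 0;
    cnt.clear(); offs.clear();
    for_each_canonical(s, n, k, [&](uint64_t km, int rpos) {
      ++valid;
      auto it = xp->map.find(km);
      if (it != xp->map.end())
        for (auto& pr : it->second) {
          ++cnt[pr.first];
          long long key = (long long)pr.first * 1000000LL +
                          (long long)(pr.second - rpos + 100000);
          ++offs[key];
        }
    });
    if (valid == 0 || cnt.empty()) continue;
    int best = 0, best_cnt = -1;
    for (auto& c : cnt) {
      if (c.second > best_cnt ||
          (c.second == best_cnt && tie_rank[c.first - 1] < tie_rank[best - 1])) {
        best = c.first; best_cnt = c.second;
      }
    }
    if ((double)best_cnt / (double)valid < min_frac) continue;
    // modal offset for the winning target
    int best_votes = -1; long long best_key = -1;
    for (auto& o : offs) {
      if (o.first / 1000000LL != best) continue;
      if (o.second > best_votes || (o.second == best_votes && o.first < best_key)) {
        best_votes = o.second; best_key = o.first;
      }
    }
    int start0 = (int)(best_key % 1000000LL) - 100000;
    out_tgt[i] = best;
    out_start[i] = start0 < 0 ? 1 : start0 + 1;
  }
  return List::create(_["target"] = out_tgt, _["start"] = out_start);
}

// Per-read count of valid k-mers (helper for tests / denominators).
// [[Rcpp::export]]
IntegerVector valid_kmer_counts(CharacterVector reads, int k) {
  IntegerVector out(reads.size());
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    const char* s = CHAR(STRING_ELT(reads, i));
    int n = (int)LENGTH(STRING_ELT(reads, i));
    out[i] = count_valid_kmers(s, n, k);
  }
  return out;
}
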