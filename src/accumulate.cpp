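#include <Rcpp.h>
using namespace Rcpp;

// Per-site pair score. Alleles for sample i at site l occupy
// alleles[maxp*(i + n*l) .. +maxp-1], padded with -1; ploidy 0 == missing.
// Phased-vs-phased calls of equal ploidy compare positionally; any other
// pairing uses the multiset rule d = 1 - |intersection|/p.
static inline double score_calls(const int *a, const int *b, int pa, int pb,
                                 bool pha, bool phb, bool *mixed) {
  if (pa != pb) { *mixed = true; return 0.0; }
  const int p = pa;
  if (pha && phb) {
    int diff = 0;
    for (int t = 0; t < p; ++t) if (a[t] != b[t]) ++diff;
    return (double)diff / p;
  }
  // multiset intersection via sorted merge; ploidy is tiny (1-8)
  int sa[8], sb[8];
  for (int t = 0; t < p; ++t) { sa[t] = a[t]; sb[t] = b[t]; }
  std::sort(sa, sa + p);
  std::sort(sb, sb + p);
  int shared = 0, ia = 0, ib = 0;
  while (ia < p && ib < p) {
    if (sa[ia] == sb[ib]) { ++shared; ++ia; ++ib; }
    else if (sa[ia] < sb[ib]) ++ia;
    else ++ib;
  }
  return 1.0 - (double)shared / p;
}

// Accumulates one chunk of sites into upper-triangle partial sums.
// Pair (i,j), i<j (0-based), lives at index i + j*(j-1)/2 (column-major
// upper triangle). Pairs are partitioned into `workers` contiguous blocks;
// each pair belongs to exactly one block and its sites are visited in
// stream order, so results are identical for any worker count.
// counters: [0] pair-site comparisons attempted, [1] mixed-ploidy skips.
// [[Rcpp::export(name = ".acc_chunk_cpp")]]
List acc_chunk_cpp(IntegerVector alleles, IntegerVector ploidy,
                   LogicalVector phased, int n, int maxp, int nsites,
                   NumericVector weights, int workers) {
  const R_xlen_t npair = (R_xlen_t)n * (n - 1) / 2;
  NumericVector sum_d(npair), used(npair);
  double comparisons = 0.0, mixed_skips = 0.0;
  if (workers < 1) workers = 1;
  if (workers > npair) workers = (int)npair;

  const int *al = INTEGER(alleles);
  const int *pl = INTEGER(ploidy);
  const int *ph = LOGICAL(phased);
  const double *w = REAL(weights);

  // enumerate pairs once in accumulator order
  std::vector<int> pi(npair), pj(npair);
  {
    R_xlen_t k = 0;
    for (int j = 1; j < n; ++j)
      for (int i = 0; i < j; ++i) { pi[k] = i; pj[k] = j; ++k; }
  }

  for (int b = 0; b < workers; ++b) {
    const R_xlen_t lo = npair * b / workers;
    const R_xlen_t hi = npair * (b + 1) / workers;
    for (int l = 0; l < nsites; ++l) {
      const double wl = w[l];
      if (wl == 0.0) continue;
      const R_xlen_t off = (R_xlen_t)maxp * n * l;
      for (R_xlen_t k = lo; k < hi; ++k) {
        comparisons += 1.0;
        const int i = pi[k], j = pj[k];
        const int pa = pl[i + (R_xlen_t)n * l];
        const int pb = pl[j + (R_xlen_t)n * l];
        if (pa == 0 || pb == 0) continue;  // missing call
        bool mixed = false;
        const double d = score_calls(al + off + (R_xlen_t)maxp * i,
                                     al + off + (R_xlen_t)maxp * j, pa, pb,
                                     ph[i + (R_xlen_t)n * l] != 0,
                                     ph[j + (R_xlen_t)n * l] != 0, &mixed);
        if (mixed) { mixed_skips += wl; continue; }
        sum_d[k] += wl * d;
        used[k] += wl;
      }
    }
  }
  return List::create(_["sum_d"] = sum_d, _["used"] = used,
                      _["comparisons"] = comparisons,
                      _["mixed_skips"] = mixed_skips);
}
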