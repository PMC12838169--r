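#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// One-sided EHH walk from a core SNP.
//
// A is sites x haplotypes (0/1). carriers holds 0-based haplotype column
// indices sharing the core allele. Starting one marker away from the core
// we refine the partition of carriers into identical extended-haplotype
// classes and emit, at each visited marker,
//   EHH(x) = sum_h C(k_h, 2) / C(n_c, 2).
// The walk stops at the first marker where EHH < min_ehh (that marker is
// still emitted: it is the final integration node) or at the chromosome
// end. truncated reports which of the two happened.

// [[Rcpp::export(name = ".ehh_side")]]
List ehh_side(const IntegerMatrix &A, const IntegerVector &carriers,
              int core, int step, double min_ehh) {
  const int S = A.nrow();
  const int n = carriers.size();
  const double denom = (double)n * (n - 1) / 2.0;

  std::vector<int> cls(n, 0);          // class id per carrier
  int n_classes = 1;
  std::vector<double> ehh;
  std::vector<int> sites;
  std::vector<int> remap;
  bool truncated = false;

  for (int j = core + step; j >= 0 && j < S; j += step) {
    // refine classes by the allele at marker j
    remap.assign(2 * n_classes, -1);
    int next_id = 0;
    for (int t = 0; t < n; ++t) {
      int key = 2 * cls[t] + A(j, carriers[t]);
      if (remap[key] < 0) remap[key] = next_id++;
      cls[t] = remap[key];
    }
    n_classes = next_id;

    std::vector<int> cnt(n_classes, 0);
    for (int t = 0; t < n; ++t) ++cnt[cls[t]];
    double num = 0.0;
    for (int h = 0; h < n_classes; ++h)
      num += (double)cnt[h] * (cnt[h] - 1) / 2.0;
    double e = num / denom;
    ehh.push_back(e);
    sites.push_back(j + 1);            // 1-based site index
    if (e < min_ehh) { truncated = true; break; }
  }

  return List::create(_["ehh"] = NumericVector(ehh.begin(), ehh.end()),
                      _["sites"] = IntegerVector(sites.begin(), sites.end()),
                      _["truncated"] = truncated);
}
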