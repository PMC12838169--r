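#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Forward Wright-Fisher generations on a haplotype store.
//
// H is sites x haplotypes (one column per haplotype) so a gamete is a
// contiguous column; entries are 0 (ancestral) / 1 (derived). All
// randomness comes from R's RNG stream, so set.seed() in the caller makes
// the run reproducible.
//
// Mutation: per generation the number of events is Poisson(M * S * mu);
// each event picks a uniform (haplotype, site) and flips 0 -> 1 only when
// the derived allele is currently absent population-wide at that site
// (single origin at any observation time; back mutation never occurs).
//
// Recombination: crossovers per meiosis ~ Poisson(rho * chrom_len),
// breakpoints uniform on (0, chrom_len].
//
// Selection: additive fitness 1, 1+s, 1+2s by the parent's dosage at
// sweep_idx (0-based; -1 disables).
//
// stop_at_target > 0 stops after the first generation where the derived
// frequency at sweep_idx reaches the target. reintroduce re-seeds a single
// copy whenever the sweep allele is lost (conditioning on establishment).

static int pos_to_site(const std::vector<double> &pos, double bp) {
  // first site with position > bp (segment [begin, idx) comes from the
  // current source haplotype)
  return (int)(std::upper_bound(pos.begin(), pos.end(), bp) - pos.begin());
}

// [[Rcpp::export(name = ".wf_generations")]]
List wf_generations(IntegerMatrix H, NumericVector positions,
                    double chrom_len, int n_gen, double mu, double rho,
                    int sweep_idx, double s, double stop_at_target,
                    bool reintroduce) {
  const int S = H.nrow();
  const int M = H.ncol();            // haplotypes (2 * diploids)
  const int N = M / 2;               // diploids
  std::vector<double> pos(positions.begin(), positions.end());

  std::vector<int> cur(H.begin(), H.end());      // column-major S x M
  std::vector<int> nxt((size_t)S * M);

  // derived-allele count per site, maintained across generations
  std::vector<int> dcount(S, 0);
  for (int j = 0; j < M; ++j) {
    const int *col = cur.data() + (size_t)j * S;
    for (int i = 0; i < S; ++i) dcount[i] += col[i];
  }

  const double xo_rate = rho * chrom_len;
  std::vector<double> cum(N);
  std::vector<double> bps;
  int gens_run = 0;
  bool hit_target = false;

  for (int g = 0; g < n_gen; ++g) {
    // parent sampling weights (selection at the sweep site)
    double tot = 0.0;
    for (int p = 0; p < N; ++p) {
      double w = 1.0;
      if (sweep_idx >= 0 && s > 0.0) {
        int dos = cur[(size_t)(2 * p) * S + sweep_idx] +
                  cur[(size_t)(2 * p + 1) * S + sweep_idx];
        w = 1.0 + s * dos;
      }
      tot += w;
      cum[p] = tot;
    }

    for (int c = 0; c < M; ++c) {     // one gamete per child haplotype
      double u = unif_rand() * tot;
      int p = (int)(std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
      if (p >= N) p = N - 1;
      int a = 2 * p, b = 2 * p + 1;
      if (unif_rand() < 0.5) std::swap(a, b);
      const int *pa = cur.data() + (size_t)a * S;
      const int *pb = cur.data() + (size_t)b * S;
      int *child = nxt.data() + (size_t)c * S;

      int k = (int)R::rpois(xo_rate);
      if (k == 0) {
        std::copy(pa, pa + S, child);
      } else {
        bps.resize(k);
        for (int t = 0; t < k; ++t) bps[t] = unif_rand() * chrom_len;
        std::sort(bps.begin(), bps.end());
        int from = 0;
        const int *src = pa;
        for (int t = 0; t < k; ++t) {
          int cut = pos_to_site(pos, bps[t]);
          if (cut > from) std::copy(src + from, src + cut, child + from);
          from = cut;
          src = (src == pa) ? pb : pa;
        }
        if (from < S) std::copy(src + from, src + S, child + from);
      }
    }

    // recount derived alleles in the offspring generation
    std::fill(dcount.begin(), dcount.end(), 0);
    for (int j = 0; j < M; ++j) {
      const int *col = nxt.data() + (size_t)j * S;
      for (int i = 0; i < S; ++i) dcount[i] += col[i];
    }

    // mutation on the offspring
    int n_mut = (int)R::rpois((double)M * (double)S * mu);
    for (int t = 0; t < n_mut; ++t) {
      int i = (int)(unif_rand() * S); if (i >= S) i = S - 1;
      int j = (int)(unif_rand() * M); if (j >= M) j = M - 1;
      if (sweep_idx >= 0 && i == sweep_idx) continue;  // reserved site
      if (dcount[i] == 0) { nxt[(size_t)j * S + i] = 1; dcount[i] = 1; }
    }

    // conditioning: re-seed a lost sweep allele as a fresh single copy
    if (sweep_idx >= 0 && reintroduce && dcount[sweep_idx] == 0) {
      int j = (int)(unif_rand() * M); if (j >= M) j = M - 1;
      nxt[(size_t)j * S + sweep_idx] = 1;
      dcount[sweep_idx] = 1;
    }

    cur.swap(nxt);
    ++gens_run;

    if (sweep_idx >= 0 && stop_at_target > 0.0 &&
        (double)dcount[sweep_idx] / (double)M >= stop_at_target) {
      hit_target = true;
      break;
    }
  }

  IntegerMatrix out(S, M);
  std::copy(cur.begin(), cur.end(), out.begin());
  double sweep_freq = NA_REAL;
  if (sweep_idx >= 0) sweep_freq = (double)dcount[sweep_idx] / (double)M;
  return List::create(_["H"] = out, _["generations_run"] = gens_run,
                      _["sweep_freq"] = sweep_freq,
                      _["hit_target"] = hit_target);
}
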