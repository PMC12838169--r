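---
title: "Methods: the iHS selection scan and its synthetic test-bed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the iHS selection scan and its synthetic test-bed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The model

`ihsscan` scans phased diploid haplotype panels for the footprint of
recent positive selection. A beneficial allele rising quickly through a
population carries its chromosomal background with it; carriers of the
derived allele therefore share an unusually long identical haplotype
compared with carriers of the ancestral allele at the same site. The
integrated haplotype score quantifies this contrast per SNP.

## EHH, iHH, uniHS, iHS

For core SNP $s$ and allele class $C \in \{A, D\}$ with $n_c \ge 2$
carriers, extended haplotype homozygosity at physical offset $x$ is

$$\mathrm{EHH}_C(x) = \frac{\sum_h \binom{k_h}{2}}{\binom{n_c}{2}},$$

where the $k_h$ are the sizes of the groups of carriers identical at
every marker between the core and $x$ (exact 0/1 string comparison, no
mismatch allowance). $\mathrm{EHH}_C(0) = 1$ and the statistic is
nonincreasing outward because extending the interval can only refine the
partition.

Each flank is walked marker by marker until EHH first drops below 0.05
(that marker is kept as the final node) or the chromosome ends, and
integrated by trapezoids over base pairs:

$$\mathrm{iHH}_C(s) = \int_0^{d_{\max}} \mathrm{EHH}_C(x)\,dx, \qquad
\mathrm{uniHS}(s) = \ln \frac{\mathrm{iHH}_A(s)}{\mathrm{iHH}_D(s)}.$$

Both flanks are summed by default; a `sides = "right"` switch gives the
literal one-sided reading of the defining integral. Because uniHS depends
strongly on the derived allele frequency (rare alleles are young and ride
long haplotypes), scores are standardized within 20 equal-width DAF bins
on (0, 1):

$$\mathrm{iHS}_{std}(s) = \frac{\mathrm{uniHS}(s) - \mu_{bin}}{\sigma_{bin}},$$

with the population (divide-by-$n$) standard deviation — the convention
is stated here because sources rarely say which they use. Significance is
the two-sided normal tail, $-\log_{10}(2\Phi(-|\mathrm{iHS}_{std}|))$,
and candidate regions cluster SNPs with $|\mathrm{iHS}_{std}| > 2$ lying
within 100 kb of each other.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `min_ehh` | 0.05 | EHH truncation threshold; flanks failing to decay below it before a chromosome end are `edge_flagged` |
| `min_maf` | 0.05 | scorable-core minor allele frequency (strict `<` rejects) |
| `n_bins` | 20 | equal-width DAF bins; `binning = "count"` gives equal-count quantile bins |
| `min_bin_n` | 10 | bins thinner than this merge into the nearest bin (logged) |
| `threshold` | 2 | candidate score magnitude |
| `cluster_gap_kb` | 100 | maximum gap between clustered significant SNPs |

Edge-flagged records are excluded from the bin moments by default
(`include_edge = TRUE` reverses this) but still receive a standardized
score; the acceptance-style tail statistics count only non-edge records.
Sites with DAF exactly 0 or 1, or with fewer than two carriers of either
allele, are unscorable and skipped before binning. Distances are physical
base pairs throughout — no genetic map is assumed.

# Numerical choices and degenerate inputs

- **Trapezoid vs. step integration.** EHH is, strictly, a right-continuous
  step function of offset (it changes only at markers), under which iHH
  would be exactly invariant to inserting a monomorphic marker. We follow
  standard practice (and the stated contract) and integrate the
  piecewise-linear interpolant; inserting a monomorphic marker then moves
  iHH by $O(\text{spacing})$ — the property suite asserts EHH-value
  invariance exactly and iHH within 1%.
- **Zero-width integrals** (single-point curves) return 0 with a warning;
  a record with a nonpositive iHH on either allele is dropped rather than
  scored.
- **Degenerate bins** with zero uniHS spread yield `NA` scores and a
  warning instead of infinities.
- **HWE exact test.** The p-value is the two-sided-by-probability-ordering
  exact conditional test, computed from the closed-form distribution of
  the heterozygote count given allele counts via log-gamma arithmetic.
  A tie tolerance of one part in $10^{12}$ keeps equal-probability
  configurations in the rejection sum. The independent oracle in the test
  suite rebuilds the same distribution through the ratio recurrence.
- **Boundary semantics** mirror the quoted QC rules: depth and mapping
  quality are inclusive (`>= 4`, `<= 200`, `>= 20`), MAF and missing rate
  are strict (`< 0.05` fails, `> 0.10` fails). The SNP spacing rule is a
  deterministic left-to-right scan: the upstream survivor stays the
  comparator, the downstream SNP is rejected. The indel window is
  symmetric (`|pos - indel| <= 3`).
- **Depth scope.** Whether coverage bounds apply per site or per sample is
  genuinely ambiguous in pipelines that mix callers; the default compares
  the site-level depth, with `depth_scope = "sample"` comparing the mean
  per-sample depth when a depth matrix is available.
- **Ti/Tv averaging.** The per-cohort "average Ti/Tv" is the mean of the
  per-individual count ratios, not the ratio of mean counts; the two
  differ in the second decimal on realistic tables and published tables
  use the former.

# The synthetic world

`simulate_panel()` is a forward-in-time diploid Wright–Fisher simulator:

- **Mutation** falls on a fixed grid of `n_sites` positions at rate `mu`
  per site, gamete and generation. A site holds at most one derived-allele
  origin at any time; a site whose derived allele is lost may be hit again
  later (without this, the finite grid would deplete during burn-in), and
  back mutation never occurs, so 0/1 polarization is always unambiguous.
- **Recombination** draws Poisson(`rho * chrom_length_bp`) crossovers per
  meiosis with uniform breakpoints.
- **Selection** is additive at one reserved site (fitnesses
  1, 1+s, 1+2s). The sweep allele is seeded at `sweep_start_freq` at
  generation `sweep_intro_gen`; earlier generations are neutral burn-in
  that builds standing variation. `condition_on_sweep = TRUE` re-seeds a
  lost allele as a fresh single copy — i.e., the run is conditioned on
  establishment from a single origin, the standard device for generating
  hard sweeps without re-running burn-in — and `sweep_target_freq` stops
  the run once the allele reaches a target frequency, yielding "swept to
  ≥ 0.9" panels by construction.
- One integer seed drives a single RNG stream; identical config + seed
  gives bit-identical panels.

Default rates (`mu = 1.2e-4`, `rho = 5e-7` per bp) are *scaled desk
values*, not goose biology: they compress a population's worth of
diversity into a few megabases and a few hundred generations so that a
laptop test reaches mutation–drift equilibrium. The study population this
emulates gives no usable calibration (no deposited data, unknown Ne), so
the defaults were chosen once to make panels that look like real phased
panels at the summary level — a 1/i-shaped frequency spectrum, LD decaying
over tens of kilobases, Ti/Tv near vertebrate values (the REF/ALT base
assignment is transition-biased at 0.7) — and are not revisited.

## What a green test does and does not establish

The generator emulates: neutral equilibrium diversity, drift, crossover
LD structure, hard selective sweeps, and phased biallelic output with
known ancestral states. It does **not** emulate: sequencing or phasing
error, missing genotypes, demographic history (bottlenecks, structure,
migration), gene conversion, or multi-chromosome genomes. A passing suite
therefore establishes the *statistic and its plumbing* — not robustness
to the artefacts of real resequencing data, which upstream QC is assumed
to remove.

## The two stochastic acceptance worlds

*Null calibration* uses the stated cohort: 50 diploids, 10 seeds, and a
24 Mb / 24,000-site grid at `mu = 1.7e-4` chosen so the scan scores about
2,000 SNPs per genome (~19,500 pooled). The pooled fraction of
$|\mathrm{iHS}| > 2$ is required to sit within three binomial standard
errors of $2\Phi(-2) \approx 0.0455$. This checks the standardization
really is calibrated — within-bin moments of 0/1 are true by
construction, but the *tail* fraction only matches the normal value if
the within-bin uniHS distribution is itself near-Gaussian.

*Sweep recovery* conditions 20 replicates on an additive sweep
(s = 0.1) from a single copy to frequency ≥ 0.9 and requires the sweep
site to fall inside an extracted candidate region in a majority. The
population here is 300 diploids on a 9 Mb chromosome. That size is a
*power requirement*, not a convenience: the detectable contrast is
roughly the ratio of the neutral pair coalescence time (≈ 2N
generations) to the conditioned sweep duration (≈ 60–150 generations at
s = 0.1). At N = 50 the two are comparable and *no* haplotype-length
statistic can separate swept from neutral backgrounds; at N = 300 the
ratio is ≈ 5 and the sweep site scores around −2 to −3 after
standardization. The 9 Mb length keeps the hitchhiking footprint
(~100 kb) to ~2% of scored sites so that the DAF-bin moments remain
essentially neutral — the desk-scale stand-in for standardizing against a
whole genome.

# Design decisions that were genuinely open

- **Forward WF rather than coalescent**: direct, auditable, and supports
  selection and conditioning trivially at desk scale.
- **Two-flank integration** with a one-sided switch: the defining
  integral is written one-sided, but haplotype extension is symmetric and
  the two-flank sum is what the field's tooling computes.
- **Equal-width DAF bins** (equal-count available by config): with ~20
  bins and thousands of SNPs the choice is immaterial to the moments, and
  equal-width keeps bin boundaries interpretable.
- **Exact HWE test rather than chi-square**: at 15 diploids the
  chi-square approximation is unusable.
- **IBS distance** as the allele-sharing distance
  (mean of |dosage difference| / 2 over co-called sites): the upstream
  tool's exact formula is undocumented and this is the standard
  definition; pairs with no co-called sites are flagged `NA`, never
  silently 0.
- **ROH parameters** follow PLINK-style defaults (50-SNP windows, ≤ 1
  heterozygote, ≥ 25 SNPs, ≥ 300 kb, 100 kb max gap, 5% window support),
  all exposed, since the emulated study reports none.
- **LD site filters** default to the upstream tool's published settings
  (`max_het = 0.1`, `max_miss = 0.3`); synthetic-panel pipelines override
  `max_het` because phased panels without genotyping error routinely
  exceed 10% heterozygosity at common sites. Unphased input falls back to
  a two-locus EM haplotype-frequency estimate, flagged in the output
  metadata.

# Known limitations

- Single-chromosome panel container; multi-chromosome studies run the
  scan per chromosome and standardize jointly by pooling records before
  `standardize_ihs()`.
- The simulator's conditioning device (re-seeding) slightly biases sweep
  durations short relative to unconditioned successful sweeps.
- `read_phased_vcf()` accepts only fully phased, complete genotypes —
  phasing and imputation are upstream concerns by contract.
- iHS has little power for sweeps that are nearly fixed (few ancestral
  carriers) or very young in small populations; see the power argument
  above.
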