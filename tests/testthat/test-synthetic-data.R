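test_that("identical config and seed give bit-identical panels", {
  cfg <- sweep_sim_config(n_diploids = 8, n_sites = 300,
                          chrom_length_bp = 3e5, mu = 5e-4, rho = 1e-6,
                          n_generations = 60, seed = 99)
  p1 <- simulate_panel(cfg)
  p2 <- simulate_panel(cfg)
  expect_identical(p1$alleles, p2$alleles)
  expect_identical(p1$positions_bp, p2$positions_bp)
  expect_identical(p1$ref, p2$ref)
})

test_that("config invariants are enforced", {
  expect_error(sweep_sim_config(n_diploids = 1), "n_diploids")
  expect_error(sweep_sim_config(n_sites = 1), "n_sites")
  expect_error(sweep_sim_config(sweep_site_bp = 1e9,
                                chrom_length_bp = 1e6), "outside")
  expect_error(sweep_sim_config(sweep_site_bp = 100, sweep_start_freq = 1),
               "sweep_start_freq")
  expect_error(
    simulate_panel(sweep_sim_config(n_diploids = 4, n_sites = 10,
                                    chrom_length_bp = 1e4, mu = 0,
                                    n_generations = 5, seed = 1)),
    "raise mu")
})

test_that("neutral final frequency of an allele started at 0.5 is a martingale", {
  # brute-force replicate oracle: under s = 0 the expected final frequency
  # equals the starting frequency
  freqs <- numeric(0)
  for (r in 1:500) {
    p <- tryCatch(
      simulate_panel(sweep_sim_config(
        n_diploids = 10, n_sites = 40, chrom_length_bp = 1e5, mu = 1.5e-3,
        rho = 1e-6, n_generations = 25, sel_coeff = 0,
        sweep_site_bp = 5e4, sweep_start_freq = 0.5, seed = 10000 + r)),
      error = function(e) NULL)
    if (!is.null(p)) freqs <- c(freqs, attr(p, "sweep_freq"))
  }
  expect_gt(length(freqs), 450)
  se <- stats::sd(freqs) / sqrt(length(freqs))
  expect_lt(abs(mean(freqs) - 0.5), 3 * se + 1e-12)
})

test_that("selection raises the mean final sweep-allele frequency", {
  mean_freq <- function(s, base_seed) {
    f <- numeric(0)
    for (r in 1:200) {
      p <- tryCatch(
        simulate_panel(sweep_sim_config(
          n_diploids = 10, n_sites = 40, chrom_length_bp = 1e5,
          mu = 1.5e-3, rho = 1e-6, n_generations = 25, sel_coeff = s,
          sweep_site_bp = 5e4, sweep_start_freq = 0.5,
          seed = 20000 + r)),
        error = function(e) NULL)
      if (!is.null(p)) f <- c(f, attr(p, "sweep_freq"))
    }
    mean(f)
  }
  expect_gt(mean_freq(0.1, 0), mean_freq(0, 0))
})

test_that("neutral site-frequency spectrum decreases in derived count", {
  # brute-force replicate average at small n
  counts <- rep(0, 9)                     # derived copies 1..9 of 10
  for (r in 1:400) {
    p <- tryCatch(
      simulate_panel(sweep_sim_config(
        n_diploids = 5, n_sites = 200, chrom_length_bp = 2e5, mu = 1e-3,
        rho = 1e-6, n_generations = 100, seed = 30000 + r)),
      error = function(e) NULL)
    if (is.null(p)) next
    k <- colSums(p$alleles)
    counts <- counts + tabulate(k, nbins = 9)
  }
  expect_true(all(diff(counts[1:5]) < 0))
  expect_gt(stats::cor(counts, 1 / (1:9), method = "spearman"), 0.9)
})

test_that("completed sweeps leave excess haplotype homozygosity among carriers", {
  found <- FALSE
  for (seed in 1:5) {
    p <- simulate_panel(sweep_sim_config(
      n_diploids = 30, n_sites = 2000, chrom_length_bp = 2e6, mu = 1.5e-4,
      rho = 1e-7, n_generations = 500, sel_coeff = 0.1, sweep_site_bp = 1e6,
      sweep_start_freq = 1 / 60, sweep_intro_gen = 300,
      sweep_target_freq = 0.85, condition_on_sweep = TRUE,
      seed = 40000 + seed))
    freq <- attr(p, "sweep_freq")
    sp <- attr(p, "sweep_site_bp")
    if (is.na(sp) || freq <= 0.8 || freq >= 1) next
    core <- match(sp, p$positions_bp)
    if ((1 - freq) * nrow(p$alleles) < 2) next
    found <- TRUE
    ihh_d <- integrate_ihh(compute_ehh(p, core, "D"))
    ihh_a <- integrate_ihh(compute_ehh(p, core, "A"))
    expect_gt(ihh_d, ihh_a)
    break
  }
  expect_true(found)
})

test_that("VCF round trip is lossless, including ancestral-equals-ALT sites", {
  A <- rbind(c(0L, 1L, 1L), c(1L, 0L, 1L), c(0L, 0L, 0L), c(1L, 1L, 0L))
  p <- haplotype_panel(A, c(100L, 250L, 900L), chrom_id = "chr7",
                       ref = c("A", "C", "G"), alt = c("G", "T", "A"),
                       anc_is_ref = c(TRUE, FALSE, TRUE))
  f <- withr::local_tempfile(fileext = ".vcf")
  write_phased_vcf(p, f)
  lines <- readLines(f)
  recs <- lines[!startsWith(lines, "#")]
  expect_length(recs, 3)
  # ancestral = ALT at site 2: AA must name the ALT base and GT coding is
  # inverted relative to the ancestral/derived matrix
  fields <- strsplit(recs[2], "\t")[[1]]
  expect_equal(fields[8], "AA=T")
  expect_equal(fields[10:11], c("0|1", "1|0"))
  p2 <- read_phased_vcf(f)
  expect_identical(p2$alleles, p$alleles)
  expect_identical(p2$positions_bp, p$positions_bp)
  expect_identical(p2$anc_is_ref, p$anc_is_ref)
  expect_identical(p2$sample_ids, p$sample_ids)

  p3 <- simulate_panel(sweep_sim_config(n_diploids = 6, n_sites = 100,
                                        chrom_length_bp = 1e5, mu = 8e-4,
                                        n_generations = 60, seed = 5))
  f3 <- withr::local_tempfile(fileext = ".vcf")
  write_phased_vcf(p3, f3)
  p4 <- read_phased_vcf(f3)
  expect_identical(p4$alleles, p3$alleles)
  expect_identical(p4$ref, p3$ref)
})

test_that("site-table fixture honours class probabilities and seed", {
  t1 <- make_site_table_fixture(5, c(intergenic = 1), 50, seed = 3)
  expect_true(all(t1$sites$annotation_class == "intergenic"))

  probs <- c(intronic = 0.4, intergenic = 0.26, synonymous = 0.34)
  t2 <- make_site_table_fixture(4, probs, 10000, seed = 12,
                                chrom_length_bp = 1e7)
  frac <- table(t2$sites$annotation_class)[names(probs)] / 10000
  se <- sqrt(probs * (1 - probs) / 10000)
  expect_true(all(abs(frac - probs) < 3 * se))

  t3 <- make_site_table_fixture(4, probs, 100, seed = 8)
  t4 <- make_site_table_fixture(4, probs, 100, seed = 8)
  expect_identical(t3$genotypes, t4$genotypes)
  expect_error(make_site_table_fixture(4, c(), 10), "empty")
  expect_error(make_site_table_fixture(4, c(a = 0.5, b = 0.6), 10), "sum")
})
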