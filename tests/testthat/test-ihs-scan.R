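test_that("EHH is 1 for identical carriers and combinatorial otherwise", {
  # all derived carriers identical across the chromosome
  A <- rbind(matrix(1L, 4, 5), matrix(rep(c(0L, 1L, 0L, 0L, 1L), 2),
                                      2, 5, byrow = TRUE))
  A[5:6, 3] <- 0L                        # core: rows 1-4 carry derived
  p <- haplotype_panel(A, c(100L, 200L, 300L, 400L, 500L))
  cv <- compute_ehh(p, 3, "D")
  expect_true(all(cv$ehh == 1))
  expect_false(cv$truncated_left)
  expect_false(cv$truncated_right)

  # 4 carriers whose extensions form classes {2, 1, 1}: EHH = 1/6
  B <- cbind(c(1L, 1L, 1L, 1L, 0L, 0L),
             c(0L, 0L, 1L, 0L, 0L, 0L),
             c(1L, 1L, 0L, 0L, 1L, 1L))
  pb <- haplotype_panel(B, c(100L, 200L, 300L))
  cvb <- compute_ehh(pb, 1, "D", min_ehh = 0)
  # at offset 100 classes are {3, 1} -> (3 + 0) / 6; at 200 {2, 1, 1} -> 1/6
  expect_equal(cvb$ehh[cvb$offsets_bp == 100], 3 / 6)
  expect_equal(cvb$ehh[cvb$offsets_bp == 200], 1 / 6)
})

test_that("EHH is monotone nonincreasing outward", {
  set.seed(31)
  for (r in 1:10) {
    rp <- random_panel(10, 15)
    for (al in c("A", "D")) {
      cv <- compute_ehh(rp$panel, rp$core, al, min_ehh = 0)
      right <- cv$ehh[cv$offsets_bp >= 0]
      left <- rev(cv$ehh[cv$offsets_bp <= 0])
      expect_true(all(diff(right) <= 1e-12))
      expect_true(all(diff(left) <= 1e-12))
    }
  }
})

test_that("fewer than two carriers is an error", {
  A <- rbind(c(1L, 0L), c(0L, 1L), c(0L, 0L), c(0L, 1L))
  p <- haplotype_panel(A, c(10L, 20L))
  expect_error(compute_ehh(p, 1, "D"), "fewer than 2 carriers")
})

test_that("iHH integration: rectangle, trapezoid, fine-grid oracle", {
  curve <- structure(list(offsets_bp = c(0, 400, 1000), ehh = c(1, 1, 1),
                          truncated_left = FALSE, truncated_right = FALSE),
                     class = "ehh_curve")
  expect_equal(integrate_ihh(curve), 1000)       # EHH = 1 over [0, d]

  curve2 <- structure(list(offsets_bp = c(0, 1000), ehh = c(1, 0.5),
                           truncated_left = FALSE, truncated_right = TRUE),
                      class = "ehh_curve")
  expect_equal(integrate_ihh(curve2), 750)       # single trapezoid

  set.seed(13)
  off <- c(rev(-cumsum(sample(50:500, 6))), 0, cumsum(sample(50:500, 5)))
  vals <- c(rev(cumprod(stats::runif(6, 0.5, 1))), 1,
            cumprod(stats::runif(5, 0.5, 1)))
  curve3 <- structure(list(offsets_bp = off, ehh = vals,
                           truncated_left = TRUE, truncated_right = TRUE),
                      class = "ehh_curve")
  expect_equal(integrate_ihh(curve3), brute_ihh(off, vals),
               tolerance = 1e-6)
  # one-sided reading drops the left flank
  right_only <- integrate_ihh(curve3, sides = "right")
  expect_lt(right_only, integrate_ihh(curve3))
})

test_that("uniHS closed forms and antisymmetry under relabeling", {
  expect_equal(unstandardized_ihs(3, 3), 0)
  expect_equal(unstandardized_ihs(exp(1) * 2, 2), 1)
  expect_error(unstandardized_ihs(0, 1), "positive")

  p <- simulate_panel(sweep_sim_config(n_diploids = 12, n_sites = 600,
                                       chrom_length_bp = 6e5, mu = 5e-4,
                                       rho = 1e-6, n_generations = 120,
                                       seed = 77))
  rec <- ihs_scan(p, min_maf = 0.1)
  rec_f <- ihs_scan(panel_flip_alleles(p), min_maf = 0.1)
  expect_equal(rec_f$pos_bp, rec$pos_bp)
  expect_equal(rec_f$daf, 1 - rec$daf)
  expect_equal(rec_f$unihs, -rec$unihs)
  expect_equal(rec_f$ihh_a, rec$ihh_d)
})

test_that("EHH/iHH are near-invariant to inserting a monomorphic marker", {
  # a monomorphic marker refines no haplotype class, so the EHH VALUES are
  # unchanged; the trapezoidal integral shifts slightly because the new
  # node changes the piecewise-linear interpolant between its neighbours
  set.seed(55)
  rp <- random_panel(8, 10)
  p <- rp$panel
  # splice a monomorphic column between markers 4 and 5
  A2 <- cbind(p$alleles[, 1:4], 0L, p$alleles[, 5:10])
  pos2 <- c(p$positions_bp[1:4],
            as.integer(mean(p$positions_bp[4:5])), p$positions_bp[5:10])
  p2 <- haplotype_panel(A2, pos2)
  core2 <- if (rp$core >= 5) rp$core + 1L else rp$core
  for (al in c("A", "D")) {
    c1 <- compute_ehh(p, rp$core, al)
    c2 <- compute_ehh(p2, core2, al)
    expect_setequal(unique(c2$ehh), unique(c1$ehh))
    expect_equal(integrate_ihh(c2), integrate_ihh(c1), tolerance = 0.01)
  }
})

test_that("bin standardization: moments, closed form, bin arithmetic", {
  rec <- data.frame(chrom = "chr1", pos_bp = 1:3 * 1000,
                    daf = c(0.5, 0.5, 0.5), ihh_a = 1, ihh_d = 1,
                    unihs = c(-1, 0, 1), edge_flagged = FALSE)
  std <- standardize_ihs(rec, n_bins = 20, min_bin_n = 1)
  expect_equal(std$ihs_std, c(-1, 0, 1) / sqrt(2 / 3))
  expect_equal(std$ihs_std[3], 1.2247449, tolerance = 1e-6)

  # daf 0.07 falls in bin 2, range (0.05, 0.10]
  rec2 <- data.frame(chrom = "chr1", pos_bp = 1:4 * 1000,
                     daf = c(0.07, 0.07, 0.61, 0.61), ihh_a = 1, ihh_d = 1,
                     unihs = c(-1, 1, -2, 2), edge_flagged = FALSE)
  std2 <- standardize_ihs(rec2, n_bins = 20, min_bin_n = 1)
  bs <- attr(std2, "bin_stats")
  expect_true(2 %in% bs$bin)
  expect_equal(bs$daf_lo[bs$bin == 2], 0.05)
  expect_equal(bs$daf_hi[bs$bin == 2], 0.10)

  # degenerate bin with zero spread is flagged
  rec3 <- data.frame(chrom = "chr1", pos_bp = 1:2 * 1000, daf = 0.5,
                     ihh_a = 1, ihh_d = 1, unihs = c(1, 1),
                     edge_flagged = FALSE)
  expect_warning(std3 <- standardize_ihs(rec3, min_bin_n = 1),
                 "degenerate")
  expect_true(all(is.na(std3$ihs_std)))

  # small bins merge into a neighbour and the merge is logged
  set.seed(6)
  rec4 <- data.frame(chrom = "chr1", pos_bp = 1:40 * 1000,
                     daf = c(rep(0.07, 3), stats::runif(37, 0.3, 0.7)),
                     ihh_a = 1, ihh_d = 1, unihs = stats::rnorm(40),
                     edge_flagged = FALSE)
  std4 <- standardize_ihs(rec4, n_bins = 20, min_bin_n = 5)
  expect_gt(length(attr(std4, "merges")), 0)
})

test_that("significance transform values and monotonicity", {
  rec <- data.frame(ihs_std = c(0, 2, -2, 1, 3, 10))
  out <- significance(rec)
  expect_equal(out$logp[1], 0)
  expect_equal(out$logp[2], -log10(2 * stats::pnorm(-2)), tolerance = 1e-12)
  expect_equal(out$logp[2], 1.342, tolerance = 1e-3)
  expect_equal(out$logp[2], out$logp[3])
  o <- order(abs(rec$ihs_std))
  expect_true(all(diff(out$logp[o][c(1, 2, 4, 5, 6)]) > 0))
  expect_true(is.finite(out$logp[6]))
})

test_that("candidate extraction clusters by gap", {
  rec <- data.frame(chrom = "chr1", pos_bp = c(1e6, 1.05e6, 1.3e6),
                    ihs_std = c(2.5, -2.2, 3))
  out <- extract_candidates(rec, threshold = 2, cluster_gap_kb = 100)
  expect_equal(nrow(out), 2)
  expect_equal(out$start_bp, c(1e6, 1.3e6))
  expect_equal(out$end_bp, c(1.05e6, 1.3e6))
  expect_equal(out$n_snps, c(2L, 1L))

  none <- extract_candidates(data.frame(chrom = "chr1", pos_bp = 1,
                                        ihs_std = 1.5))
  expect_equal(nrow(none), 0)
})

test_that("candidate annotation reports gene features only", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\ttest\tgene\t900000\t1200000\t.\t+\t.\tID=geneA;Name=geneA",
    "chr1\ttest\tmRNA\t900000\t1200000\t.\t+\t.\tID=geneA.t1;Parent=geneA",
    "chr1\ttest\texon\t900000\t950000\t.\t+\t.\tID=geneA.e1;Parent=geneA.t1",
    "chr1\ttest\tgene\t5000000\t5100000\t.\t-\t.\tID=geneB;Name=geneB"),
    gff)
  regions <- data.frame(chrom = "chr1",
                        start_bp = c(1000000, 3000000),
                        end_bp = c(1050000, 3100000),
                        peak_ihs = c(2.5, 2.1), n_snps = c(3L, 1L))
  out <- annotate_candidates(regions, gff)
  expect_equal(out$genes, c("geneA", ""))

  bad <- regions; bad$chrom <- "scaffold_9"
  expect_warning(annotate_candidates(bad, gff), "chromosome")
})
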