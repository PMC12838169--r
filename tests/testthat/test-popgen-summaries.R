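test_that("substitution classification follows purine/pyrimidine classes", {
  expect_equal(classify_substitution("A", "G"), "Ti")
  expect_equal(classify_substitution("A", "T"), "Tv")
  expect_equal(classify_substitution(c("C", "G", "T"), c("T", "C", "G")),
               c("Ti", "Tv", "Tv"))
  expect_error(classify_substitution("A", "N"), "A, C, G, T")
  expect_error(classify_substitution("A", "A"), "differ")
})

test_that("a printed Ti/Tv pair reproduces its published ratio", {
  tab <- reference_table("goose_variant_summary")
  ye1 <- tab[tab$sample_id == "YE.1", ]
  expect_equal(round(ye1$n_ti / ye1$n_tv, 2), 2.47)
})

test_that("individual stats satisfy the table identities", {
  set.seed(11)
  tbl <- make_site_table_fixture(8, c(intergenic = 0.5, intronic = 0.3,
                                      synonymous = 0.2), 400, seed = 11)
  st <- individual_stats(tbl)
  expect_equal(st$n_ti + st$n_tv, st$n_snp)
  expect_equal(st$n_het + st$n_hom, st$n_snp)
  ann <- rowSums(st[, grep("^ann_", names(st)), drop = FALSE])
  expect_equal(unname(ann), st$n_snp)
  expect_equal(st$titv, st$n_ti / st$n_tv)

  # a sample that is hom-ref everywhere carries no variants
  g <- cbind(c(0L, 0L, 0L), c(1L, 2L, 0L))
  st0 <- individual_stats(make_table(g))
  expect_equal(st0$n_snp, c(0L, 2L))
})

test_that("IBS distances follow allele sharing", {
  # identical genotype vectors
  g <- cbind(c(0L, 1L, 2L), c(0L, 1L, 2L))
  expect_equal(unname(ibs_distance_matrix(make_table(g))[1, 2]), 0)
  # opposite homozygotes everywhere
  g2 <- cbind(c(0L, 2L), c(2L, 0L))
  expect_equal(unname(ibs_distance_matrix(make_table(g2))[1, 2]), 1)
  # (hom-ref vs het), (hom-ref vs hom-alt), (het vs het)
  g3 <- cbind(c(0L, 0L, 1L), c(1L, 2L, 1L))
  expect_equal(unname(ibs_distance_matrix(make_table(g3))[1, 2]), 0.5)
  # semimetric properties on a random fixture
  tbl <- make_site_table_fixture(6, c(intergenic = 1), 200, seed = 2)
  d <- ibs_distance_matrix(tbl)
  expect_true(isSymmetric(d))
  expect_equal(unname(diag(d)), rep(0, 6))
  expect_true(all(d >= 0 & d <= 1))
  # a pair with no co-called sites is NA with a warning
  g4 <- cbind(c(0L, NA), c(NA, 1L))
  expect_warning(d4 <- ibs_distance_matrix(make_table(g4)), "co-called")
  expect_true(is.na(d4[1, 2]))
})

test_that("diversity statistics match closed forms and a summation oracle", {
  # p = 0.5 and p = 0 closed forms
  g <- rbind(c(0L, 2L), c(0L, 0L))
  dv <- diversity_stats(make_table(g))
  expect_equal(dv$per_site$he, c(0.5, 0))
  expect_equal(dv$per_site$pic, c(0.375, 0))
  expect_true(all(dv$per_site$he >= dv$per_site$pic))

  set.seed(5)
  tbl <- make_site_table_fixture(10, c(intergenic = 1), 20, seed = 5,
                                 missing_rate = 0.05)
  dv2 <- diversity_stats(tbl)
  # independent Fis recomputation by direct summation
  gm <- tbl$genotypes
  for (j in 1:10) {
    ok <- !is.na(gm[, j])
    p <- rowSums(gm, na.rm = TRUE)[ok] / (2 * rowSums(!is.na(gm))[ok])
    e_hom <- sum(1 - 2 * p * (1 - p))
    o_hom <- sum(gm[ok, j] != 1L)
    expect_equal(dv2$per_individual$fis[j],
                 (o_hom - e_hom) / (sum(ok) - e_hom))
  }
  expect_true(all(dv2$per_site$he <= 0.5 + 1e-12))
  # monomorphic-only input: Fis undefined
  g5 <- matrix(0L, nrow = 3, ncol = 4)
  expect_warning(dv3 <- diversity_stats(make_table(g5)), "Fis undefined")
  expect_true(all(is.na(dv3$per_individual$fis)))
})

test_that("ROH detection recovers a constructed homozygous stretch", {
  # 30 het SNPs, 100 homozygous SNPs spanning ~600 kb, 30 het SNPs
  pos <- c(seq(1000, 30000, by = 1000),
           seq(100000, 694000, by = 6000),
           seq(800000, 829000, by = 1000))
  g <- matrix(c(rep(1L, 30), rep(c(0L, 2L), 50), rep(1L, 30)), ncol = 1)
  tbl <- make_table(g, pos = as.integer(pos))
  segs <- detect_roh(tbl)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$start_bp, 100000)
  expect_equal(segs$end_bp, 694000)
  expect_equal(segs$n_snps, 100)
  expect_equal(segs$length_bp, segs$end_bp - segs$start_bp + 1L)

  # all-heterozygous individual: no segments
  g2 <- matrix(1L, nrow = 120, ncol = 1)
  expect_equal(nrow(detect_roh(make_table(g2, pos = as.integer(pos[1:120])))),
               0)

  # relaxing min_length never removes a reported segment
  relaxed <- detect_roh(tbl, min_length_kb = 50)
  key <- function(x) paste(x$sample_id, x$chrom, x$start_bp, x$end_bp)
  expect_true(all(key(segs) %in% key(relaxed)))
})

test_that("LD r2 matches haplotype-table brute force and the null level", {
  # duplicated site: perfect LD
  set.seed(4)
  A <- matrix(stats::rbinom(40 * 2, 1, 0.4), 40, 2)
  A <- cbind(A[, 1], A[, 1], A[, 2])
  p <- haplotype_panel(A, c(1000L, 2000L, 9000L))
  out <- ld_decay(p, max_dist_kb = 10, max_het = 1, bin_width_kb = 1)
  expect_equal(out$mean_r2[out$bin_hi_bp == 1000], 1)

  # brute-force 2x2 haplotype-table computation over all pairs
  set.seed(9)
  A2 <- matrix(stats::rbinom(30 * 20, 1, 0.5), 30, 20)
  keep <- colMeans(A2) > 0 & colMeans(A2) < 1
  A2 <- A2[, keep]
  p2 <- haplotype_panel(A2, sort(sample.int(5e4, ncol(A2))))
  out2 <- ld_decay(p2, max_dist_kb = 100, max_het = 1,
                   bin_width_kb = 100)      # one bin holds every pair
  brute <- c()
  pos <- p2$positions_bp
  for (i in seq_len(ncol(A2) - 1)) for (j in (i + 1):ncol(A2)) {
    n11 <- sum(A2[, i] & A2[, j]); pA <- mean(A2[, i]); pB <- mean(A2[, j])
    brute <- c(brute, (n11 / nrow(A2) - pA * pB)^2 /
                 (pA * (1 - pA) * pB * (1 - pB)))
  }
  expect_equal(out2$mean_r2, mean(brute))
  expect_equal(out2$n_pairs, length(brute))

  # permutation null: independent sites, 60 haplotypes -> E[r2] ~ 1/60
  set.seed(21)
  A3 <- matrix(stats::rbinom(60 * 250, 1, 0.3), 60, 250)
  keep3 <- colMeans(A3) > 0 & colMeans(A3) < 1
  p3 <- haplotype_panel(A3[, keep3],
                        sort(sample.int(4e5, sum(keep3))))
  out3 <- ld_decay(p3, max_dist_kb = 500, max_het = 1, bin_width_kb = 500)
  mean_r2 <- sum(out3$mean_r2 * out3$n_pairs) / sum(out3$n_pairs)
  expect_gt(mean_r2, 0.8 / 60)
  expect_lt(mean_r2, 1.4 / 60)

  # pair beyond max_dist is excluded
  A4 <- matrix(stats::rbinom(20 * 2, 1, 0.5), 20, 2)
  p4 <- haplotype_panel(A4, c(1L, 501001L))
  expect_error(ld_decay(p4, max_dist_kb = 500, max_het = 1), "no scorable")
})
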