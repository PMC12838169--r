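#' Quality-control thresholds
#'
#' Two tiers of SNP quality control: caller-side site filters (coverage,
#' mapping quality, SNP spacing, indel proximity, missingness) and
#' scan-level locus QC (minor allele frequency, missing rate,
#' Hardy-Weinberg equilibrium). Depth and mapping-quality bounds are
#' inclusive ("at least 4", "at least 20"); the MAF and missing-rate bounds
#' are strict ("less than 0.05", "exceeding 10%").
#'
#' @param min_depth,max_depth inclusive coverage-depth bounds.
#' @param min_rms_mq inclusive RMS mapping-quality minimum.
#' @param min_snp_spacing_bp minimum distance between adjacent retained
#'   SNPs; closer downstream SNPs are rejected in a left-to-right scan.
#' @param indel_exclusion_bp reject SNPs with |pos - indel_pos| <= this.
#' @param max_missing_caller caller-tier maximum missing-genotype fraction.
#' @param min_maf scan-tier minor-allele-frequency minimum (strict).
#' @param max_missing_scan scan-tier maximum missing fraction (strict).
#' @param hwe_alpha scan-tier Hardy-Weinberg exact-test alpha.
#' @param depth_scope `"site"` compares the site depth column against the
#'   bounds; `"sample"` compares the mean per-sample depth (requires a
#'   depth matrix).
#' @return an object of class `filter_config`.
#' @export
filter_config <- function(min_depth = 4, max_depth = 200, min_rms_mq = 20,
                          min_snp_spacing_bp = 5, indel_exclusion_bp = 3,
                          max_missing_caller = 0.50, min_maf = 0.05,
                          max_missing_scan = 0.10, hwe_alpha = 1e-6,
                          depth_scope = c("site", "sample")) {
  cfg <- list(min_depth = min_depth, max_depth = max_depth,
              min_rms_mq = min_rms_mq,
              min_snp_spacing_bp = min_snp_spacing_bp,
              indel_exclusion_bp = indel_exclusion_bp,
              max_missing_caller = max_missing_caller,
              min_maf = min_maf, max_missing_scan = max_missing_scan,
              hwe_alpha = hwe_alpha,
              depth_scope = match.arg(depth_scope))
  if (any(unlist(cfg[1:9]) < 0)) stop("thresholds must be nonnegative")
  if (cfg$min_maf > 0.5) stop("min_maf must lie in [0, 0.5]")
  class(cfg) <- "filter_config"
  cfg
}

new_outcome <- function(tbl, reasons) {
  reasons_chr <- vapply(reasons, paste, "", collapse = ",")
  data.frame(chrom = tbl$sites$chrom, pos = tbl$sites$pos,
             pass = reasons_chr == "", reasons = reasons_chr,
             stringsAsFactors = FALSE)
}

#' Apply caller-side site filters
#'
#' Annotates every site with all the caller-tier rules it fails:
#' `MIN_DEPTH` / `MAX_DEPTH` (inclusive coverage bounds), `LOW_MQ`
#' (inclusive RMS mapping-quality minimum), `SPACING` (a deterministic
#' left-to-right scan per chromosome: a SNP closer than the minimum spacing
#' to the last spacing-retained SNP is rejected and the upstream SNP stays
#' the comparator), `NEAR_INDEL` (symmetric window around supplied indel
#' positions) and `MISSING_CALLER` (missing-genotype fraction above the
#' caller-tier maximum).
#'
#' @param tbl a [site_table()] sorted by (chrom, pos); unsorted input is an
#'   error, never silently re-sorted.
#' @param config a [filter_config()].
#' @param indels optional data frame of indel positions (`chrom`, `pos`).
#' @return data frame with `chrom`, `pos`, `pass` and a comma-joined
#'   `reasons` column (`pass` is true iff `reasons` is empty).
#' @export
apply_caller_filters <- function(tbl, config = filter_config(),
                                 indels = NULL) {
  stopifnot(inherits(tbl, "site_table"), inherits(config, "filter_config"))
  s <- tbl$sites
  o <- order(s$chrom, s$pos)
  if (!identical(o, seq_len(nrow(s))))
    stop("sites must be sorted by (chrom, pos); refusing to re-sort")
  reasons <- vector("list", nrow(s))

  depth <- if (config$depth_scope == "sample") {
    if (is.null(tbl$depth_matrix))
      stop("depth_scope = \"sample\" requires a per-sample depth matrix")
    rowMeans(tbl$depth_matrix)
  } else s$depth
  if (!is.null(depth)) {
    low <- which(depth < config$min_depth)
    high <- which(depth > config$max_depth)
    for (i in low) reasons[[i]] <- c(reasons[[i]], "MIN_DEPTH")
    for (i in high) reasons[[i]] <- c(reasons[[i]], "MAX_DEPTH")
  }
  if (!is.null(s$rms_mq))
    for (i in which(s$rms_mq < config$min_rms_mq))
      reasons[[i]] <- c(reasons[[i]], "LOW_MQ")

  # greedy left-to-right spacing scan, independent of the other rules
  for (ch in unique(s$chrom)) {
    idx <- which(s$chrom == ch)
    last_kept <- -Inf
    for (i in idx) {
      if (s$pos[i] - last_kept < config$min_snp_spacing_bp)
        reasons[[i]] <- c(reasons[[i]], "SPACING")
      else last_kept <- s$pos[i]
    }
  }

  if (!is.null(indels) && nrow(indels)) {
    for (ch in unique(s$chrom)) {
      ip <- indels$pos[indels$chrom == ch]
      if (!length(ip)) next
      idx <- which(s$chrom == ch)
      near <- vapply(s$pos[idx],
                     function(p) any(abs(p - ip) <= config$indel_exclusion_bp),
                     TRUE)
      for (i in idx[near]) reasons[[i]] <- c(reasons[[i]], "NEAR_INDEL")
    }
  }

  miss <- rowMeans(is.na(tbl$genotypes))
  for (i in which(miss > config$max_missing_caller))
    reasons[[i]] <- c(reasons[[i]], "MISSING_CALLER")

  new_outcome(tbl, reasons)
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact conditional test: given the observed allele counts, the p-value is
#' the probability mass of all heterozygote counts whose conditional
#' probability does not exceed that of the observed count (two-sided by
#' probability ordering). Probabilities are computed from the closed-form
#' conditional distribution
#' P(n_het | n_minor, n) with log-gamma arithmetic, which is exact for any
#' cohort size.
#'
#' @param n_hom_ref,n_het,n_hom_alt genotype counts (nonnegative, sum >= 1).
#' @return p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  counts <- c(n_hom_ref, n_het, n_hom_alt)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("genotype counts must be nonnegative integers")
  n <- sum(counts)
  if (n < 1) stop("at least one genotype required")
  n_alt <- n_het + 2 * n_hom_alt
  n_minor <- min(n_alt, 2 * n - n_alt)
  if (n_minor == 0) return(1)          # monomorphic: trivially consistent

  hets <- seq.int(n_minor %% 2, n_minor, by = 2)
  # log P(n_het = h | minor count, n) up to a shared constant
  logp <- h_logprob(hets, n, n_minor)
  logp <- logp - max(logp)
  pr <- exp(logp); pr <- pr / sum(pr)
  obs <- pr[match(n_het, hets)]
  if (is.na(obs)) stop("n_het incompatible with the allele counts")
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

# log conditional probability of h heterozygotes given n diploids and
# n_minor minor alleles (unnormalized)
h_logprob <- function(h, n, n_minor) {
  n_major <- 2 * n - n_minor
  hom_min <- (n_minor - h) / 2
  hom_maj <- n - h - hom_min
  h * log(2) + lgamma(n + 1) -
    (lgamma(hom_min + 1) + lgamma(h + 1) + lgamma(hom_maj + 1))
}

#' Apply scan-level locus QC
#'
#' Flags loci with `LOW_MAF` (minor allele frequency, computed from
#' non-missing genotypes, strictly below the minimum), `MISSING_SCAN`
#' (missing fraction strictly above the maximum; a site with no calls at
#' all is flagged `MISSING_SCAN` rather than raising an error) and
#' `HWE_FAIL` (exact-test p-value below `hwe_alpha`).
#'
#' @inheritParams apply_caller_filters
#' @return data frame as in [apply_caller_filters()].
#' @export
apply_scan_qc <- function(tbl, config = filter_config()) {
  stopifnot(inherits(tbl, "site_table"), inherits(config, "filter_config"))
  g <- tbl$genotypes
  reasons <- vector("list", nrow(g))
  n_called <- rowSums(!is.na(g))
  miss <- rowMeans(is.na(g))

  for (i in seq_len(nrow(g))) {
    if (miss[i] > config$max_missing_scan)
      reasons[[i]] <- c(reasons[[i]], "MISSING_SCAN")
    if (n_called[i] == 0L) next        # MAF/HWE undefined, not an error
    gi <- g[i, !is.na(g[i, ])]
    p_alt <- sum(gi) / (2 * length(gi))
    maf <- min(p_alt, 1 - p_alt)
    if (maf < config$min_maf)
      reasons[[i]] <- c(reasons[[i]], "LOW_MAF")
    p <- hwe_exact_test(sum(gi == 0L), sum(gi == 1L), sum(gi == 2L))
    if (p < config$hwe_alpha)
      reasons[[i]] <- c(reasons[[i]], "HWE_FAIL")
  }
  new_outcome(tbl, reasons)
}
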