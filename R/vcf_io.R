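#' Write a phased haplotype panel to VCF 4.2
#'
#' Serializes one biallelic record per site with phased `GT` (`|`
#' separator) and an `INFO/AA` tag naming the ancestral base. The matrix's
#' 0/1 ancestral/derived coding is translated to REF/ALT coding via the
#' panel's `anc_is_ref` flags, so the ancestral allele may be the ALT base.
#'
#' @param panel a [haplotype_panel()] carrying `ref`/`alt` bases (panels
#'   without bases get A/G placeholders with the ancestral allele as REF).
#' @param path output file path (plain text `.vcf`).
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(panel, path) {
  stopifnot(inherits(panel, "haplotype_panel"))
  if (is.null(panel$ref)) {
    panel$ref <- rep("A", ncol(panel$alleles))
    panel$alt <- rep("G", ncol(panel$alleles))
    panel$anc_is_ref <- rep(TRUE, ncol(panel$alleles))
  }
  n <- length(panel$sample_ids)
  clen <- attr(panel, "chrom_length_bp")
  if (is.null(clen) || is.na(clen)) clen <- max(panel$positions_bp)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=ihsscan",
    sprintf("##contig=<ID=%s,length=%d>", panel$chrom_id, as.integer(clen)),
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$sample_ids), collapse = "\t"))

  # 0 = ancestral -> REF/ALT index depends on which base is ancestral
  h1 <- panel$alleles[seq(1L, 2L * n, by = 2L), , drop = FALSE]
  h2 <- panel$alleles[seq(2L, 2L * n, by = 2L), , drop = FALSE]
  flip <- !panel$anc_is_ref
  if (any(flip)) {
    h1[, flip] <- 1L - h1[, flip, drop = FALSE]
    h2[, flip] <- 1L - h2[, flip, drop = FALSE]
  }
  aa <- ifelse(panel$anc_is_ref, panel$ref, panel$alt)
  gt_cols <- matrix(paste0(h1, "|", h2), nrow = n)   # samples x sites
  gt <- apply(gt_cols, 2L, paste, collapse = "\t")
  rec <- paste(panel$chrom_id, panel$positions_bp, ".", panel$ref, panel$alt,
               ".", "PASS", paste0("AA=", aa), "GT", gt, sep = "\t")
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Read a phased VCF into a haplotype panel
#'
#' Reads a VCF (via `VariantAnnotation`) holding phased biallelic SNVs and
#' polarizes alleles with the `INFO/AA` ancestral tag (or a sidecar data
#' frame with columns `chrom`, `pos`, `aa`). Records with missing or
#' unphased genotypes, non-SNV alleles, or an ancestral base matching
#' neither REF nor ALT are dropped with a message.
#'
#' @param path VCF file path.
#' @param ancestral optional data frame (`chrom`, `pos`, `aa`) used when
#'   the VCF has no `AA` tag.
#' @return a [haplotype_panel()].
#' @export
read_phased_vcf <- function(path, ancestral = NULL) {
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  if (length(unique(chrom)) > 1L)
    stop("multi-chromosome VCFs are not supported by the panel container")
  pos <- GenomicRanges::start(rr)
  ref <- as.character(rr$REF)
  altl <- rr$ALT
  alt <- vapply(seq_along(altl), function(i) {
    a <- altl[[i]]
    if (length(a) == 1L) as.character(a) else NA_character_
  }, "")

  aa <- NULL
  info <- VariantAnnotation::info(vcf)
  if ("AA" %in% colnames(info)) {
    aa <- toupper(as.character(info$AA))
  } else if (!is.null(ancestral)) {
    key <- match(paste(chrom, pos), paste(ancestral$chrom, ancestral$pos))
    aa <- toupper(as.character(ancestral$aa[key]))
  } else stop("no INFO/AA tag and no ancestral sidecar given")

  gt <- VariantAnnotation::geno(vcf)$GT        # sites x samples
  phased <- apply(gt, 1L, function(g) all(grepl("^[01]\\|[01]$", g)))
  snv <- ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  polarized <- !is.na(aa) & (aa == ref | aa == alt)
  keep <- phased & snv & polarized
  if (!all(keep))
    message(sum(!keep), " record(s) dropped (unphased/missing, non-SNV, ",
            "or unpolarizable)")
  if (!any(keep)) stop("no usable phased biallelic records")

  gt <- gt[keep, , drop = FALSE]
  h1 <- matrix(as.integer(substr(gt, 1L, 1L)), nrow = nrow(gt))
  h2 <- matrix(as.integer(substr(gt, 3L, 3L)), nrow = nrow(gt))
  anc_is_ref <- aa[keep] == ref[keep]
  flip <- !anc_is_ref
  h1[flip, ] <- 1L - h1[flip, , drop = FALSE]   # to ancestral/derived coding
  h2[flip, ] <- 1L - h2[flip, , drop = FALSE]

  n_sites <- nrow(gt); n_samp <- ncol(gt)
  alleles <- matrix(0L, nrow = 2L * n_samp, ncol = n_sites)
  alleles[seq(1L, 2L * n_samp, by = 2L), ] <- t(h1)
  alleles[seq(2L, 2L * n_samp, by = 2L), ] <- t(h2)
  haplotype_panel(alleles, pos[keep], chrom_id = chrom[1L],
                  sample_ids = colnames(gt), ref = ref[keep],
                  alt = alt[keep], anc_is_ref = anc_is_ref)
}
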