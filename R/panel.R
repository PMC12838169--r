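#' Phased haplotype panel
#'
#' The substrate of the selection scan: a binary matrix of phased
#' haplotypes (rows) by segregating sites (columns), coded 0 = ancestral,
#' 1 = derived, together with strictly increasing 1-based physical
#' positions. Each sample owns two consecutive haplotype rows.
#'
#' @param alleles integer matrix in \{0,1\}, one row per haplotype (an even
#'   number of rows), one column per site.
#' @param positions_bp strictly increasing integer vector of 1-based
#'   physical positions, one per site.
#' @param chrom_id chromosome label.
#' @param sample_ids sample labels, one per diploid (half the row count of
#'   `alleles`); generated when missing.
#' @param ref,alt optional per-site REF/ALT bases (single characters among
#'   A, C, G, T) used when serializing to VCF.
#' @param anc_is_ref optional logical per site: is the ancestral (0-coded)
#'   allele the REF base? Defaults to all `TRUE` when `ref`/`alt` are
#'   supplied.
#'
#' @return an object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(alleles, positions_bp, chrom_id = "chr1",
                            sample_ids = NULL, ref = NULL, alt = NULL,
                            anc_is_ref = NULL) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  if (nrow(alleles) %% 2L != 0L)
    stop("haplotype count must be even (two rows per diploid sample)")
  if (!all(alleles %in% c(0L, 1L)))
    stop("alleles must be coded 0 (ancestral) / 1 (derived)")
  positions_bp <- as.integer(positions_bp)
  if (length(positions_bp) != ncol(alleles))
    stop("one position per site required")
  if (length(positions_bp) > 1L && any(diff(positions_bp) <= 0L))
    stop("positions must be strictly increasing")
  if (any(positions_bp < 1L)) stop("positions are 1-based (>= 1)")
  n <- nrow(alleles) / 2L
  if (is.null(sample_ids)) sample_ids <- sprintf("S%02d", seq_len(n))
  if (length(sample_ids) != n)
    stop("need one sample id per diploid (", n, ")")
  if (!is.null(ref)) {
    stopifnot(length(ref) == ncol(alleles), length(alt) == ncol(alleles))
    bad <- !(ref %in% c("A", "C", "G", "T")) | !(alt %in% c("A", "C", "G", "T"))
    if (any(bad)) stop("ref/alt must be single bases among A, C, G, T")
    if (any(ref == alt)) stop("ref and alt must differ at every site")
    if (is.null(anc_is_ref)) anc_is_ref <- rep(TRUE, ncol(alleles))
  }
  structure(
    list(alleles = alleles, positions_bp = positions_bp,
         chrom_id = chrom_id, sample_ids = sample_ids,
         ref = ref, alt = alt, anc_is_ref = anc_is_ref),
    class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf(
    "haplotype_panel: %d haplotypes (%d diploids) x %d sites on %s [%s..%s bp]\n",
    nrow(x$alleles), nrow(x$alleles) / 2L, ncol(x$alleles), x$chrom_id,
    format(min(x$positions_bp)), format(max(x$positions_bp))))
  daf <- panel_daf(x)
  cat(sprintf("  derived allele frequency: median %.3f, range %.3f..%.3f\n",
              stats::median(daf), min(daf), max(daf)))
  invisible(x)
}

#' Derived allele frequency per site
#'
#' @param panel a [haplotype_panel()].
#' @return numeric vector of derived-allele frequencies.
#' @export
panel_daf <- function(panel) colMeans(panel$alleles)

#' Diploid genotype dosages of a panel
#'
#' Collapses the two haplotype rows of each sample into a derived-allele
#' dosage in \{0, 1, 2\}.
#'
#' @param panel a [haplotype_panel()].
#' @return integer matrix, sites x samples.
#' @export
panel_genotypes <- function(panel) {
  n <- length(panel$sample_ids)
  g <- t(panel$alleles[seq(1L, 2L * n, by = 2L), , drop = FALSE] +
           panel$alleles[seq(2L, 2L * n, by = 2L), , drop = FALSE])
  colnames(g) <- panel$sample_ids
  g
}

#' Swap the ancestral/derived labelling of every site
#'
#' Utility for antisymmetry checks: relabels each allele (0 <-> 1).
#'
#' @param panel a [haplotype_panel()].
#' @return a [haplotype_panel()] with flipped coding.
#' @export
panel_flip_alleles <- function(panel) {
  panel$alleles <- 1L - panel$alleles
  if (!is.null(panel$anc_is_ref)) panel$anc_is_ref <- !panel$anc_is_ref
  panel
}

#' Restrict a panel to a subset of sites
#' @param panel a [haplotype_panel()].
#' @param keep logical or integer index over sites.
#' @return a [haplotype_panel()].
#' @export
panel_subset <- function(panel, keep) {
  panel$alleles <- panel$alleles[, keep, drop = FALSE]
  panel$positions_bp <- panel$positions_bp[keep]
  for (f in c("ref", "alt", "anc_is_ref"))
    if (!is.null(panel[[f]])) panel[[f]] <- panel[[f]][keep]
  panel
}
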