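#' Genome-wide unstandardized iHS scan
#'
#' Runs [compute_ehh()] / [integrate_ihh()] for both alleles of every
#' scorable core SNP in a phased panel. A core is scorable when its derived
#' allele frequency lies strictly inside (0, 1), each allele has at least
#' two carriers, and (optionally) the minor allele frequency passes
#' `min_maf`. EHH is evaluated over all panel markers, so monomorphic-free
#' QC should be done upstream. Records where either flank of either allele
#' reaches a chromosome end before decaying below `min_ehh` are flagged
#' `edge_flagged`.
#'
#' @param panel a [haplotype_panel()].
#' @param min_ehh EHH truncation threshold.
#' @param min_maf minor-allele-frequency threshold for cores (strict; 0
#'   scores every segregating site).
#' @param sides integrate both flanks (default) or only the right flank.
#' @return data frame with one row per scored SNP: `chrom`, `pos_bp`,
#'   `daf`, `ihh_a`, `ihh_d`, `unihs`, `edge_flagged`.
#' @export
ihs_scan <- function(panel, min_ehh = 0.05, min_maf = 0.05,
                     sides = c("both", "right")) {
  stopifnot(inherits(panel, "haplotype_panel"))
  sides <- match.arg(sides)
  M <- nrow(panel$alleles)
  cnt <- colSums(panel$alleles)          # integer derived-allele counts
  daf <- cnt / M
  maf <- pmin(cnt, M - cnt) / M
  cores <- which(cnt >= 2L & (M - cnt) >= 2L & maf >= min_maf)
  A <- t(panel$alleles)
  pos <- panel$positions_bp
  S <- length(pos)

  out <- vector("list", length(cores))
  for (ii in seq_along(cores)) {
    core <- cores[ii]
    edge <- FALSE
    ihh <- c(A_allele = 0, D_allele = 0)
    ok <- TRUE
    for (k in 1:2) {
      al <- c(0L, 1L)[k]
      carriers <- which(panel$alleles[, core] == al)
      lft <- .ehh_side(A, carriers - 1L, core - 1L, -1L, min_ehh)
      rgt <- .ehh_side(A, carriers - 1L, core - 1L, 1L, min_ehh)
      if (!rgt$truncated || (sides == "both" && !lft$truncated)) edge <- TRUE
      v <- 0
      if (length(rgt$sites))
        v <- v + trapz_bp(c(0, pos[rgt$sites] - pos[core]), c(1, rgt$ehh))
      if (sides == "both" && length(lft$sites))
        v <- v + trapz_bp(c(0, pos[core] - pos[lft$sites]), c(1, lft$ehh))
      if (v <= 0) ok <- FALSE
      ihh[k] <- v
    }
    if (!ok) next                        # zero-width integral: unscorable
    out[[ii]] <- data.frame(chrom = panel$chrom_id, pos_bp = pos[core],
                            daf = daf[core], ihh_a = ihh[1], ihh_d = ihh[2],
                            # log difference (not log of ratio) keeps
                            # allele-relabeling antisymmetry bit-exact
                            unihs = log(ihh[1]) - log(ihh[2]),
                            edge_flagged = edge, stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out))
    return(data.frame(chrom = character(), pos_bp = integer(),
                      daf = numeric(), ihh_a = numeric(), ihh_d = numeric(),
                      unihs = numeric(), edge_flagged = logical(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

trapz_bp <- function(x, y) {
  if (length(x) < 2L) return(0)
  sum(diff(x) * (utils::head(y, -1L) + utils::tail(y, -1L)) / 2)
}

#' Standardize uniHS within derived-allele-frequency bins
#'
#' Stratifies scored SNPs into `n_bins` equal-width (default) or
#' equal-count DAF bins on (0, 1) and standardizes uniHS within each bin
#' with the bin mean and population (divide-by-n) standard deviation:
#' `ihs_std = (unihs - mu_bin) / sigma_bin`. Bins holding fewer than
#' `min_bin_n` records are merged with their nearest non-empty neighbour
#' (merges are recorded in the returned bin table). Edge-flagged records
#' are excluded from the bin statistics by default but still receive a
#' standardized score from their bin's moments.
#'
#' @param records data frame from [ihs_scan()].
#' @param n_bins number of DAF bins.
#' @param min_bin_n minimum records per bin before merging.
#' @param binning `"width"` (equal-width on (0,1)) or `"count"`
#'   (equal-count quantile bins).
#' @param include_edge include edge-flagged records in the bin statistics.
#' @return `records` with added `ihs_std` and `daf_bin` (final bin
#'   assignment after merging) columns, plus attribute
#'   `bin_stats`: data frame (`bin`, `daf_lo`, `daf_hi`, `n`, `mu_bin`,
#'   `sigma_bin`) and attribute `merges` (character log).
#' @export
standardize_ihs <- function(records, n_bins = 20, min_bin_n = 10,
                            binning = c("width", "count"),
                            include_edge = FALSE) {
  binning <- match.arg(binning)
  stopifnot(nrow(records) > 0)
  if (binning == "width") {
    edges <- seq(0, 1, length.out = n_bins + 1)
  } else {
    edges <- unique(stats::quantile(records$daf,
                                    probs = seq(0, 1, length.out = n_bins + 1),
                                    names = FALSE))
    edges[1] <- 0; edges[length(edges)] <- 1
  }
  bin <- findInterval(records$daf, edges, left.open = TRUE,
                      rightmost.closed = TRUE)
  bin[bin < 1L] <- 1L                      # daf in first open interval

  use <- if (include_edge) rep(TRUE, nrow(records)) else !records$edge_flagged
  merges <- character(0)
  # merge underfilled bins (by records used for the statistics) into the
  # nearest bin by index until all used bins are big enough
  repeat {
    tab <- tapply(use, bin, sum)
    ids <- as.integer(names(tab))
    small <- ids[which(tab < min_bin_n)]
    if (!length(small) || length(ids) == 1L) break
    b <- small[1L]
    others <- setdiff(ids, b)
    tgt <- others[which.min(abs(others - b))]
    merges <- c(merges,
                sprintf("bin %d (n=%d) merged into bin %d", b, tab[as.character(b)], tgt))
    bin[bin == b] <- tgt
  }

  mu <- tapply(records$unihs[use], bin[use], mean)
  sig <- tapply(records$unihs[use], bin[use],
                function(v) sqrt(mean((v - mean(v))^2)))
  key <- as.character(bin)
  mu_i <- mu[key]; sig_i <- sig[key]
  if (any(!is.na(sig_i) & sig_i == 0))
    warning("degenerate bin with zero spread; scores undefined there")
  ihs <- (records$unihs - mu_i) / ifelse(sig_i > 0, sig_i, NA_real_)
  records$ihs_std <- as.numeric(ihs)
  records$daf_bin <- bin

  ids <- sort(unique(bin))
  bs <- data.frame(bin = ids,
                   daf_lo = edges[pmin(ids, length(edges) - 1L)],
                   daf_hi = edges[pmin(ids + 1L, length(edges))],
                   n = as.integer(tapply(use, bin, sum)[as.character(ids)]),
                   mu_bin = as.numeric(mu[as.character(ids)]),
                   sigma_bin = as.numeric(sig[as.character(ids)]))
  attr(records, "bin_stats") <- bs
  attr(records, "merges") <- merges
  records
}

#' Two-sided normal significance transform
#'
#' Under the neutral standard-normal null,
#' `logp = -log10(2 * Phi(-|ihs_std|))`; strictly increasing in the score
#' magnitude and 0 at a score of 0.
#'
#' @param records data frame with an `ihs_std` column.
#' @return `records` with an added `logp` column.
#' @export
significance <- function(records) {
  stopifnot("ihs_std" %in% names(records))
  # log-scale evaluation keeps large scores finite and accurate
  records$logp <- -(stats::pnorm(-abs(records$ihs_std), log.p = TRUE) +
                      log(2)) / log(10)
  records
}

#' Extract candidate regions from standardized scores
#'
#' Significant SNPs (`|ihs_std| > threshold`) are clustered per chromosome
#' whenever consecutive hits lie within `cluster_gap_kb`; each region spans
#' the minimum and maximum hit positions.
#'
#' @param records standardized records (with `ihs_std`).
#' @param threshold score magnitude threshold (strict).
#' @param cluster_gap_kb maximum gap between consecutive hits in a region.
#' @return data frame: `chrom`, `start_bp`, `end_bp`, `peak_ihs`
#'   (max |score|), `n_snps`; zero rows when nothing exceeds the threshold.
#' @export
extract_candidates <- function(records, threshold = 2, cluster_gap_kb = 100) {
  hits <- records[!is.na(records$ihs_std) &
                    abs(records$ihs_std) > threshold, , drop = FALSE]
  if (!nrow(hits))
    return(data.frame(chrom = character(), start_bp = integer(),
                      end_bp = integer(), peak_ihs = numeric(),
                      n_snps = integer(), stringsAsFactors = FALSE))
  hits <- hits[order(hits$chrom, hits$pos_bp), ]
  out <- list()
  for (ch in unique(hits$chrom)) {
    h <- hits[hits$chrom == ch, ]
    grp <- cumsum(c(0L, as.integer(diff(h$pos_bp) > cluster_gap_kb * 1000)))
    for (g in unique(grp)) {
      hh <- h[grp == g, ]
      out[[length(out) + 1L]] <-
        data.frame(chrom = ch, start_bp = min(hh$pos_bp),
                   end_bp = max(hh$pos_bp),
                   peak_ihs = max(abs(hh$ihs_std)), n_snps = nrow(hh),
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Attach overlapping gene models to candidate regions
#'
#' Intersects candidate regions (1-based closed intervals) with the
#' `gene`-type features of a GFF3 file (nested mRNA/exon features are
#' ignored) and attaches the overlapping gene identifiers. A
#' chromosome-name mismatch between regions and gene models triggers a
#' warning with per-chromosome counts.
#'
#' @param regions data frame from [extract_candidates()].
#' @param gff_path path to a GFF3 file with `gene` features.
#' @return `regions` with an added `genes` column (comma-joined ids; empty
#'   string when nothing overlaps).
#' @export
annotate_candidates <- function(regions, gff_path) {
  gff <- rtracklayer::import(gff_path)
  genes <- gff[gff$type == "gene"]
  if (nrow(regions) == 0L) {
    regions$genes <- character(0)
    return(regions)
  }
  shared <- intersect(unique(regions$chrom),
                      as.character(GenomicRanges::seqnames(genes)))
  if (!length(shared)) {
    tab_r <- table(regions$chrom)
    tab_g <- table(as.character(GenomicRanges::seqnames(genes)))
    warning("no shared chromosome names between regions (",
            paste(names(tab_r), tab_r, sep = ":", collapse = ", "),
            ") and gene models (",
            paste(names(tab_g), tab_g, sep = ":", collapse = ", "), ")")
  }
  gr <- GenomicRanges::GRanges(regions$chrom,
                               IRanges::IRanges(regions$start_bp,
                                                regions$end_bp))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(gr, genes))
  ids <- genes$ID
  if (is.null(ids)) ids <- genes$Name
  if (is.null(ids)) ids <- as.character(seq_along(genes))
  regions$genes <- vapply(seq_len(nrow(regions)), function(i) {
    g <- ids[S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == i]]
    paste(unique(g), collapse = ",")
  }, "")
  regions
}
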