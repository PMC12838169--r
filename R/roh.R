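#' Detect runs of homozygosity
#'
#' Sliding-window scan in the PLINK style: windows of `window_snps`
#' consecutive SNPs are "homozygosity-compatible" when they contain at most
#' `max_het_in_window` heterozygous calls (missing calls are tolerated); a
#' SNP is in-ROH when the fraction of windows overlapping it that are
#' compatible exceeds `hit_fraction`. Maximal in-ROH runs are split at
#' inter-SNP gaps above `max_gap_kb` and reported when they contain at
#' least `min_snps` SNPs and span at least `min_length_kb` (1-based closed
#' span, `length = end - start + 1`). Chromosomes with fewer SNPs than the
#' window size are scanned with a single all-SNP window.
#'
#' @param tbl a [site_table()] sorted by (chrom, pos).
#' @param window_snps window size in SNPs.
#' @param max_het_in_window maximum heterozygous calls per compatible
#'   window.
#' @param min_snps minimum SNPs per reported segment.
#' @param min_length_kb minimum segment span in kb.
#' @param max_gap_kb split runs at inter-SNP gaps above this.
#' @param hit_fraction in-ROH window-support threshold.
#' @return data frame of segments: `sample_id`, `chrom`, `start_bp`,
#'   `end_bp`, `n_snps`, `length_bp`.
#' @export
detect_roh <- function(tbl, window_snps = 50, max_het_in_window = 1,
                       min_snps = 25, min_length_kb = 300,
                       max_gap_kb = 100, hit_fraction = 0.05) {
  stopifnot(inherits(tbl, "site_table"))
  s <- tbl$sites
  if (is.unsorted(order(s$chrom, s$pos)))
    stop("sites must be sorted by (chrom, pos)")
  segs <- list()
  for (ch in unique(s$chrom)) {
    idx <- which(s$chrom == ch)
    pos <- s$pos[idx]
    n <- length(idx)
    w <- min(window_snps, n)
    for (j in seq_along(tbl$sample_ids)) {
      het <- as.integer(!is.na(tbl$genotypes[idx, j]) &
                          tbl$genotypes[idx, j] == 1L)
      # het count per window via cumulative sums
      cs <- c(0L, cumsum(het))
      n_win <- n - w + 1L
      win_ok <- (cs[(w + 1L):(n + 1L)] - cs[1L:n_win]) <= max_het_in_window
      # per-SNP support: windows k..k+w-1 overlap SNP i for k in
      # [max(1, i-w+1), min(i, n_win)]
      ok_cs <- c(0L, cumsum(as.integer(win_ok)))
      lo <- pmax(1L, seq_len(n) - w + 1L)
      hi <- pmin(seq_len(n), n_win)
      n_over <- hi - lo + 1L
      n_ok <- ok_cs[hi + 1L] - ok_cs[lo]
      in_roh <- n_over > 0L & (n_ok / pmax(1L, n_over)) > hit_fraction

      r <- rle(in_roh)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (k in which(r$values)) {
        run <- starts[k]:ends[k]
        # split at large gaps
        gaps <- diff(pos[run]) > max_gap_kb * 1000
        grp <- cumsum(c(0L, as.integer(gaps)))
        for (g in unique(grp)) {
          sub <- run[grp == g]
          span <- pos[sub[length(sub)]] - pos[sub[1L]] + 1L
          if (length(sub) >= min_snps && span >= min_length_kb * 1000)
            segs[[length(segs) + 1L]] <-
              data.frame(sample_id = tbl$sample_ids[j], chrom = ch,
                         start_bp = pos[sub[1L]],
                         end_bp = pos[sub[length(sub)]],
                         n_snps = length(sub), length_bp = span,
                         stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(segs))
    return(data.frame(sample_id = character(), chrom = character(),
                      start_bp = integer(), end_bp = integer(),
                      n_snps = integer(), length_bp = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, segs)
}
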