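#' Linkage-disequilibrium decay curve
#'
#' Pairwise r-squared for all intra-chromosome site pairs within
#' `max_dist_kb`, averaged in distance bins. From a phased
#' [haplotype_panel()], r2 is computed from haplotype frequencies,
#' `r2 = (p_AB - p_A p_B)^2 / (p_A (1-p_A) p_B (1-p_B))`; from an unphased
#' [site_table()], two-locus haplotype frequencies are first estimated by
#' expectation-maximization and the result is flagged in the returned
#' metadata. Sites with a heterozygous-genotype fraction above `max_het` or
#' a missing fraction above `max_miss` are excluded; pairs involving a
#' monomorphic site are skipped.
#'
#' @param x a [haplotype_panel()] or [site_table()].
#' @param max_dist_kb maximum pair distance (strict upper bound in bp is
#'   `max_dist_kb * 1000`, inclusive).
#' @param max_het exclude sites with heterozygote fraction above this.
#' @param max_miss exclude sites with missing-genotype fraction above this.
#' @param bin_width_kb distance-bin width.
#' @return data frame with `bin_lo_bp`, `bin_hi_bp`, `bin_mid_bp`,
#'   `mean_r2`, `n_pairs`; attribute `phased` records the input route.
#' @export
ld_decay <- function(x, max_dist_kb = 500, max_het = 0.1, max_miss = 0.3,
                     bin_width_kb = 10) {
  if (inherits(x, "haplotype_panel")) {
    H <- x$alleles                       # haplotypes x sites
    pos <- x$positions_bp
    gt <- panel_genotypes(x)             # for the het-fraction filter
    het_frac <- rowMeans(gt == 1L)
    miss_frac <- rep(0, length(pos))
    phased <- TRUE
  } else if (inherits(x, "site_table")) {
    if (length(unique(x$sites$chrom)) > 1L)
      stop("one chromosome at a time")
    gt <- x$genotypes
    pos <- x$sites$pos
    het_frac <- rowMeans(gt == 1L, na.rm = TRUE)
    miss_frac <- rowMeans(is.na(gt))
    phased <- FALSE
  } else stop("x must be a haplotype_panel or site_table")

  usable <- het_frac <= max_het & miss_frac <= max_miss
  keep <- which(usable)
  if (length(keep) < 2L) stop("fewer than 2 usable sites")
  pos <- pos[keep]
  max_bp <- max_dist_kb * 1000

  dists <- numeric(0); r2s <- numeric(0)
  for (a in seq_len(length(keep) - 1L)) {
    b <- which(pos > pos[a] & pos - pos[a] <= max_bp)
    b <- b[b > a]
    if (!length(b)) next
    if (phased) {
      ha <- H[, keep[a]]
      pA <- mean(ha)
      if (pA == 0 || pA == 1) next
      hb <- H[, keep[b], drop = FALSE]
      pB <- colMeans(hb)
      pAB <- colMeans(hb * ha)
      denom <- pA * (1 - pA) * pB * (1 - pB)
      ok <- denom > 0
      r2 <- (pAB[ok] - pA * pB[ok])^2 / denom[ok]
      dists <- c(dists, (pos[b] - pos[a])[ok])
      r2s <- c(r2s, r2)
    } else {
      for (bb in b) {
        r2 <- em_r2(gt[keep[a], ], gt[keep[bb], ])
        if (!is.na(r2)) {
          dists <- c(dists, pos[bb] - pos[a])
          r2s <- c(r2s, r2)
        }
      }
    }
  }
  if (!length(r2s)) stop("no scorable pairs within max_dist")
  bin <- ceiling(dists / (bin_width_kb * 1000))
  agg <- tapply(r2s, bin, mean)
  cnt <- tapply(r2s, bin, length)
  bidx <- as.integer(names(agg))
  out <- data.frame(bin_lo_bp = (bidx - 1L) * bin_width_kb * 1000,
                    bin_hi_bp = bidx * bin_width_kb * 1000,
                    bin_mid_bp = (bidx - 0.5) * bin_width_kb * 1000,
                    mean_r2 = as.numeric(agg),
                    n_pairs = as.integer(cnt))
  attr(out, "phased") <- phased
  out
}

# two-locus EM haplotype-frequency estimate from unphased dosages;
# returns r2 or NA for monomorphic/degenerate pairs
em_r2 <- function(ga, gb, max_iter = 50, tol = 1e-8) {
  ok <- !is.na(ga) & !is.na(gb)
  ga <- ga[ok]; gb <- gb[ok]
  n <- length(ga)
  if (n < 2L) return(NA_real_)
  pA <- mean(ga) / 2; pB <- mean(gb) / 2
  if (pA %in% c(0, 1) || pB %in% c(0, 1)) return(NA_real_)
  # haplotypes: 11, 10, 01, 00 (1 = ALT); start at linkage equilibrium
  f <- c(pA * pB, pA * (1 - pB), (1 - pA) * pB, (1 - pA) * (1 - pB))
  dh <- ga == 1L & gb == 1L                 # double heterozygotes
  n_dh <- sum(dh)
  # haplotype counts contributed by unambiguous genotype combinations
  c11 <- sum((ga == 2L) * (gb == 2L) * 2 + (ga == 2L) * (gb == 1L) +
               (ga == 1L) * (gb == 2L))
  c10 <- sum((ga == 2L) * (gb == 0L) * 2 + (ga == 2L) * (gb == 1L) +
               (ga == 1L) * (gb == 0L))
  c01 <- sum((ga == 0L) * (gb == 2L) * 2 + (ga == 0L) * (gb == 1L) +
               (ga == 1L) * (gb == 2L))
  c00 <- sum((ga == 0L) * (gb == 0L) * 2 + (ga == 0L) * (gb == 1L) +
               (ga == 1L) * (gb == 0L))
  for (it in seq_len(max_iter)) {
    # split double hets between cis (11/00) and trans (10/01)
    cis <- f[1] * f[4]; trans <- f[2] * f[3]
    w <- if (cis + trans > 0) cis / (cis + trans) else 0.5
    h11 <- c11 + n_dh * w
    h00 <- c00 + n_dh * w
    h10 <- c10 + n_dh * (1 - w)
    h01 <- c01 + n_dh * (1 - w)
    fnew <- c(h11, h10, h01, h00) / (2 * n)
    if (max(abs(fnew - f)) < tol) { f <- fnew; break }
    f <- fnew
  }
  pAB <- f[1]
  D <- pAB - pA * pB
  denom <- pA * (1 - pA) * pB * (1 - pB)
  if (denom <= 0) return(NA_real_)
  D^2 / denom
}
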