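# Independent oracles used by the unit and acceptance suites. These stay
# deliberately naive (explicit pair enumeration, recurrences, fine-grid
# sums) and share no code with the implementation paths they check.

# EHH by explicit enumeration of all carrier pairs over the interval from
# the core to each marker, walking outward until the value drops below
# min_ehh (that marker kept) or the chromosome ends.
brute_ehh <- function(panel, core, allele, min_ehh = 0.05) {
  a <- if (allele == "D") 1L else 0L
  A <- panel$alleles
  carriers <- which(A[, core] == a)
  n <- length(carriers)
  S <- ncol(A)
  walk <- function(js) {
    vals <- numeric(0); trunc <- FALSE
    for (j in js) {
      rng <- min(core, j):max(core, j)
      cnt <- 0L
      for (x in seq_len(n - 1L)) for (y in (x + 1L):n)
        if (all(A[carriers[x], rng] == A[carriers[y], rng]))
          cnt <- cnt + 1L
      e <- cnt / choose(n, 2)
      vals <- c(vals, e)
      if (e < min_ehh) { trunc <- TRUE; break }
    }
    list(ehh = vals, truncated = trunc)
  }
  right <- walk(if (core < S) (core + 1L):S else integer(0))
  left <- walk(if (core > 1L) (core - 1L):1L else integer(0))
  list(right = right, left = left)
}

# area under a piecewise-linear EHH curve by Riemann summation on a 1-bp
# grid (both flanks)
brute_ihh <- function(offsets_bp, ehh) {
  total <- 0
  for (sgn in c(1, -1)) {
    sel <- sgn * offsets_bp >= 0
    if (sum(sel) < 2) next
    x <- sgn * offsets_bp[sel]; y <- ehh[sel]
    o <- order(x); x <- x[o]; y <- y[o]
    grid <- seq(min(x), max(x), by = 1)
    total <- total + sum(stats::approx(x, y, xout = grid)$y) -
      (stats::approx(x, y, xout = min(x))$y +
         stats::approx(x, y, xout = max(x))$y) / 2
  }
  total
}

# Hardy-Weinberg exact p-value via the ratio recurrence over heterozygote
# counts (a different computational route from the lgamma closed form)
hwe_enum <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  n_alt <- n_het + 2 * n_hom_alt
  n_minor <- min(n_alt, 2 * n - n_alt)
  if (n_minor == 0) return(1)
  hets <- seq.int(n_minor %% 2, n_minor, by = 2)
  pr <- numeric(length(hets))
  pr[1] <- 1
  for (k in seq_len(length(hets) - 1)) {
    h <- hets[k]
    hom_min <- (n_minor - h) / 2
    hom_maj <- n - h - hom_min
    # P(h+2) / P(h)
    pr[k + 1] <- pr[k] * 4 * hom_min * hom_maj / ((h + 2) * (h + 1))
  }
  pr <- pr / sum(pr)
  obs <- pr[match(n_het, hets)]
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

# random small panel with a polymorphic core usable for both alleles
random_panel <- function(n_hap, n_sites, span = 1e5) {
  repeat {
    A <- matrix(stats::rbinom(n_hap * n_sites, 1, stats::runif(1, 0.2, 0.8)),
                n_hap, n_sites)
    core <- sample(n_sites, 1)
    if (sum(A[, core]) >= 2 && sum(1 - A[, core]) >= 2) break
  }
  list(panel = haplotype_panel(A, sort(sample.int(span, n_sites))),
       core = core)
}

# small deterministic site table builder: genotypes is a sites x samples
# matrix of dosages
make_table <- function(genotypes, pos = NULL, ref = NULL, alt = NULL,
                       depth = NULL, rms_mq = NULL, ann = NULL,
                       chrom = "chr1") {
  genotypes <- as.matrix(genotypes)
  ns <- nrow(genotypes)
  if (is.null(pos)) pos <- seq_len(ns) * 1000L
  if (is.null(ref)) ref <- rep("A", ns)
  if (is.null(alt)) alt <- rep("G", ns)
  sites <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                      stringsAsFactors = FALSE)
  if (!is.null(depth)) sites$depth <- depth
  if (!is.null(rms_mq)) sites$rms_mq <- rms_mq
  if (!is.null(ann)) sites$annotation_class <- ann
  site_table(sites, genotypes,
             sample_ids = sprintf("S%02d", seq_len(ncol(genotypes))))
}
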