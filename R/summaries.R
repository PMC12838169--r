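#' Classify a substitution as transition or transversion
#'
#' Purine-purine (A/G) and pyrimidine-pyrimidine (C/T) substitutions are
#' transitions; all other base changes are transversions.
#'
#' @param ref,alt single bases among A, C, G, T (vectorized); `ref` must
#'   differ from `alt` elementwise.
#' @return character vector of `"Ti"` / `"Tv"`.
#' @export
classify_substitution <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  ok <- ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  if (!all(ok)) stop("ref/alt must be single bases among A, C, G, T")
  if (any(ref == alt)) stop("ref and alt must differ")
  purine <- c("A", "G")
  ifelse((ref %in% purine) == (alt %in% purine), "Ti", "Tv")
}

#' Per-individual variant statistics
#'
#' For every sample, counts the sites where that sample carries at least
#' one ALT allele (its "variant sites"), split into heterozygous (one ALT
#' allele) and homozygous (two), into transitions and transversions, and
#' into annotation classes when the table carries them. Missing genotypes
#' are excluded from that sample's counts. The identities
#' `n_ti + n_tv == n_snp` and `n_het + n_hom == n_snp` hold by
#' construction.
#'
#' @param tbl a [site_table()].
#' @return data frame, one row per sample: `sample_id`, `n_snp`, `n_ti`,
#'   `n_tv`, `titv`, `n_het`, `n_hom`, plus one `ann_*` column per
#'   annotation class present.
#' @export
individual_stats <- function(tbl) {
  stopifnot(inherits(tbl, "site_table"))
  g <- tbl$genotypes
  is_ti <- classify_substitution(tbl$sites$ref, tbl$sites$alt) == "Ti"
  has_ann <- !is.null(tbl$sites$annotation_class)
  if (has_ann) {
    ann <- resolve_annotation(tbl$sites$annotation_class)
    classes <- sort(unique(ann))
  }
  out <- lapply(seq_along(tbl$sample_ids), function(j) {
    gj <- g[, j]
    var <- !is.na(gj) & gj > 0L
    n_het <- sum(gj[var] == 1L)
    n_hom <- sum(gj[var] == 2L)
    n_ti <- sum(is_ti[var])
    n_tv <- sum(!is_ti[var])
    row <- data.frame(sample_id = tbl$sample_ids[j],
                      n_snp = n_het + n_hom, n_ti = n_ti, n_tv = n_tv,
                      titv = if (n_tv > 0) n_ti / n_tv else NA_real_,
                      n_het = n_het, n_hom = n_hom,
                      stringsAsFactors = FALSE)
    if (has_ann)
      for (cl in classes)
        row[[paste0("ann_", cl)]] <- sum(ann[var] == cl)
    row
  })
  do.call(rbind, out)
}

#' Identity-by-state allele-sharing distance matrix
#'
#' Pairwise distance `mean over co-called sites of |d_i - d_j| / 2`, where
#' `d` is the ALT-allele dosage: identical genotypes share two alleles
#' (distance 0), a homozygote and a heterozygote share one (0.5), opposite
#' homozygotes share none (1). Pairs with zero co-called sites get `NA`
#' with a warning rather than a silent zero.
#'
#' @param tbl a [site_table()] with at least 2 samples.
#' @return symmetric matrix with zero diagonal and entries in \[0, 1\].
#' @export
ibs_distance_matrix <- function(tbl) {
  stopifnot(inherits(tbl, "site_table"))
  g <- tbl$genotypes
  n <- ncol(g)
  if (n < 2L) stop("need at least 2 samples")
  d <- matrix(0, n, n, dimnames = list(tbl$sample_ids, tbl$sample_ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- !is.na(g[, i]) & !is.na(g[, j])
    if (!any(ok)) {
      warning("samples ", tbl$sample_ids[i], " and ", tbl$sample_ids[j],
              " share no co-called sites; distance undefined")
      d[i, j] <- d[j, i] <- NA_real_
    } else {
      d[i, j] <- d[j, i] <- mean(abs(g[ok, i] - g[ok, j])) / 2
    }
  }
  d
}

#' Per-site diversity and per-individual inbreeding statistics
#'
#' Per site (over non-missing genotypes): observed heterozygosity `Ho`
#' (heterozygote fraction), expected heterozygosity `He = 2p(1-p)` with `p`
#' the ALT-allele frequency, and polymorphism information content
#' `PIC = 1 - p^2 - q^2 - 2 p^2 q^2`. Per individual: the inbreeding
#' coefficient `Fis = (O_hom - E_hom) / (n - E_hom)` where `O_hom` is the
#' individual's observed homozygous-site count over its non-missing sites
#' and `E_hom = sum(1 - 2 p q)` over the same sites, using the sample
#' allele frequencies. With only monomorphic sites `He` is 0 everywhere and
#' `Fis` is `NA` (flagged by a warning).
#'
#' @param tbl a [site_table()].
#' @return list with data frames `per_site` (`chrom`, `pos`, `ho`, `he`,
#'   `pic`) and `per_individual` (`sample_id`, `fis`).
#' @export
diversity_stats <- function(tbl) {
  stopifnot(inherits(tbl, "site_table"))
  g <- tbl$genotypes
  called <- !is.na(g)
  n_called <- rowSums(called)
  if (any(n_called == 0L))
    warning(sum(n_called == 0L), " site(s) with no calls; statistics NA there")
  p <- rowSums(g, na.rm = TRUE) / (2 * n_called)
  q <- 1 - p
  ho <- rowSums(g == 1L, na.rm = TRUE) / n_called
  he <- 2 * p * q
  pic <- 1 - p^2 - q^2 - 2 * p^2 * q^2
  per_site <- data.frame(chrom = tbl$sites$chrom, pos = tbl$sites$pos,
                         ho = ho, he = he, pic = pic,
                         stringsAsFactors = FALSE)

  exp_hom <- 1 - he                      # per-site expected homozygosity
  fis <- vapply(seq_along(tbl$sample_ids), function(j) {
    ok <- called[, j] & !is.na(p)
    n <- sum(ok)
    e_hom <- sum(exp_hom[ok])
    o_hom <- sum(g[ok, j] != 1L)
    if (abs(n - e_hom) < .Machine$double.eps * n) return(NA_real_)
    (o_hom - e_hom) / (n - e_hom)
  }, 0)
  if (anyNA(fis))
    warning("Fis undefined for some individuals (monomorphic-only input)")
  list(per_site = per_site,
       per_individual = data.frame(sample_id = tbl$sample_ids, fis = fis,
                                   stringsAsFactors = FALSE))
}
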