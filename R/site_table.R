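#' Per-site variant table
#'
#' A light container for per-site variant metadata plus a genotype dosage
#' matrix, the substrate of the quality-control filters and the
#' per-individual summary statistics. Genotypes are ALT-allele dosages
#' (0 = hom-ref, 1 = het, 2 = hom-alt, `NA` = missing).
#'
#' @param sites data frame with columns `chrom`, `pos`, `ref`, `alt` and
#'   optionally `depth` (site coverage), `rms_mq` (RMS mapping quality) and
#'   `annotation_class`.
#' @param genotypes integer matrix, sites x samples, dosages in
#'   \{0, 1, 2, NA\}.
#' @param sample_ids sample labels; default taken from `colnames(genotypes)`.
#' @param depth_matrix optional per-sample depth matrix (sites x samples).
#' @return an object of class `site_table`.
#' @export
site_table <- function(sites, genotypes, sample_ids = colnames(genotypes),
                       depth_matrix = NULL) {
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos", "ref", "alt") %in% names(sites)))
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  if (nrow(genotypes) != nrow(sites))
    stop("genotypes must have one row per site")
  if (!all(genotypes %in% c(0L, 1L, 2L, NA)))
    stop("genotypes must be dosages in {0, 1, 2} or NA")
  if (is.null(sample_ids))
    sample_ids <- sprintf("S%02d", seq_len(ncol(genotypes)))
  if (any(sites$pos < 1)) stop("positions are 1-based (>= 1)")
  if (any(sites$ref == sites$alt)) stop("ref and alt must differ")
  structure(list(sites = sites, genotypes = genotypes,
                 sample_ids = sample_ids, depth_matrix = depth_matrix),
            class = "site_table")
}

#' @export
print.site_table <- function(x, ...) {
  cat(sprintf("site_table: %d sites x %d samples (%s)\n",
              nrow(x$sites), length(x$sample_ids),
              paste(unique(x$sites$chrom), collapse = ", ")))
  invisible(x)
}

#' Build a site table from a haplotype panel
#'
#' Collapses phased haplotypes into genotype dosages and carries over
#' REF/ALT bases. The dosage counts the ALT allele: where the ancestral
#' allele is the ALT base the derived dosage is inverted accordingly.
#'
#' @param panel a [haplotype_panel()].
#' @return a [site_table()].
#' @export
as_site_table <- function(panel) {
  stopifnot(inherits(panel, "haplotype_panel"))
  g <- panel_genotypes(panel)               # derived-allele dosage
  if (is.null(panel$ref)) {
    ref <- rep("A", nrow(g)); alt <- rep("G", nrow(g))
    anc_is_ref <- rep(TRUE, nrow(g))
  } else {
    ref <- panel$ref; alt <- panel$alt; anc_is_ref <- panel$anc_is_ref
  }
  flip <- !anc_is_ref
  g[flip, ] <- 2L - g[flip, , drop = FALSE]  # to ALT dosage
  site_table(data.frame(chrom = panel$chrom_id, pos = panel$positions_bp,
                        ref = ref, alt = alt, stringsAsFactors = FALSE),
             g, sample_ids = panel$sample_ids)
}

#' Annotation classes in decreasing severity order
#'
#' Used to resolve multi-label sites to a single class (splice >
#' non-synonymous > synonymous > UTR > up/downstream > intronic >
#' intergenic).
#' @export
annotation_severity <- c("splice", "non_synonymous", "synonymous",
                         "utr5", "utr3", "up_down", "intronic", "intergenic")

#' Resolve multi-label annotation strings to one class
#'
#' @param classes character vector; multi-label entries are comma-joined.
#' @return character vector of single classes, picked by [annotation_severity].
#' @export
resolve_annotation <- function(classes) {
  vapply(strsplit(classes, ","), function(cl) {
    cl <- trimws(cl)
    hit <- annotation_severity[annotation_severity %in% cl]
    if (length(hit)) hit[1L] else cl[1L]
  }, "")
}

#' Generate a random annotated genotype-table fixture
#'
#' Emulates a SnpEff-annotated call set at desk scale: random per-site
#' annotation classes drawn from `class_probs`, genotypes in
#' Hardy-Weinberg proportions at a uniform random allele frequency, and
#' per-site / per-sample depth and mapping-quality fields populated so that
#' every filter rejection reason can be exercised.
#'
#' @param n_samples number of diploid samples.
#' @param class_probs named numeric vector of annotation-class
#'   probabilities; must sum to 1.
#' @param n_sites number of sites.
#' @param seed integer seed.
#' @param missing_rate per-genotype missing probability.
#' @param depth_mean,mq_mean Poisson/normal means for the site depth and
#'   RMS mapping-quality columns.
#' @param chrom_length_bp span over which positions are drawn.
#' @return a [site_table()] with `depth`, `rms_mq` and `annotation_class`
#'   columns and a per-sample `depth_matrix`.
#' @export
make_site_table_fixture <- function(n_samples, class_probs, n_sites,
                                    seed = 1L, missing_rate = 0.02,
                                    depth_mean = 30, mq_mean = 40,
                                    chrom_length_bp = 1e6) {
  if (length(class_probs) == 0L) stop("class_probs must not be empty")
  if (abs(sum(class_probs) - 1) > 1e-8)
    stop("class probabilities must sum to 1")
  set.seed(as.integer(seed))
  pos <- sort(sample.int(chrom_length_bp, n_sites))
  cls <- sample(names(class_probs), n_sites, replace = TRUE,
                prob = class_probs)
  ref <- sample(c("A", "C", "G", "T"), n_sites, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1L),
                "")
  p <- stats::runif(n_sites, 0.05, 0.5)
  g <- matrix(stats::rbinom(n_sites * n_samples, 2L,
                            rep(p, n_samples)),
              nrow = n_sites, ncol = n_samples)
  if (missing_rate > 0)
    g[stats::runif(length(g)) < missing_rate] <- NA_integer_
  dp <- matrix(stats::rpois(n_sites * n_samples, depth_mean / n_samples + 1),
               nrow = n_sites)
  sites <- data.frame(chrom = "chr1", pos = pos, ref = ref, alt = alt,
                      depth = as.integer(rowSums(dp)),
                      rms_mq = pmax(0, stats::rnorm(n_sites, mq_mean, 8)),
                      annotation_class = cls, stringsAsFactors = FALSE)
  colnames(g) <- sprintf("S%02d", seq_len(n_samples))
  site_table(sites, g, depth_matrix = dp)
}
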