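#' Bundled reference tables from a 15-bird goose resequencing cohort
#'
#' Small plain-text tables describing a conserved Yan goose population of
#' 15 males, shipped as worked-example inputs: per-individual SNP counts
#' split by transition/transversion and zygosity
#' (`"goose_variant_summary"`), per-individual SnpEff-style annotation
#' tallies (`"goose_annotation_tallies"`), and the pairwise
#' identity-by-state distance matrix with zero self-distances
#' (`"goose_ibs_matrix"`).
#'
#' @param name one of `"goose_variant_summary"`,
#'   `"goose_annotation_tallies"`, `"goose_ibs_matrix"`.
#' @return a data frame (the IBS matrix with sample ids as row names).
#' @export
reference_table <- function(name = c("goose_variant_summary",
                                     "goose_annotation_tallies",
                                     "goose_ibs_matrix")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".tsv"), package = "ihsscan",
                      mustWork = TRUE)
  if (name == "goose_ibs_matrix")
    return(utils::read.delim(path, row.names = 1, check.names = FALSE))
  utils::read.delim(path, check.names = FALSE)
}

#' Cohort-level summary of a per-individual variant table
#'
#' Recomputes the quantities a resequencing paper's summary tables print
#' from their per-individual rows: the mean SNP count, mean/maximum
#' heterozygous-site counts, the mean of the per-individual Ti/Tv ratios
#' (each ratio recomputed from the Ti and Tv counts), class means of the
#' annotation tallies and the synonymous/non-synonymous ratio of class
#' means, and the full-matrix mean identity-by-state distance (zero
#' diagonal included).
#'
#' @param variants data frame shaped like
#'   `reference_table("goose_variant_summary")`.
#' @param tallies data frame shaped like
#'   `reference_table("goose_annotation_tallies")`.
#' @param ibs square distance matrix / data frame with zero diagonal.
#' @return named list of scalars: `mean_snp`, `mean_het`, `max_het`,
#'   `mean_titv`, `mean_intergenic`, `mean_intronic`, `syn_nonsyn_ratio`,
#'   `mean_ibs`.
#' @export
cohort_summary <- function(variants = reference_table("goose_variant_summary"),
                           tallies = reference_table("goose_annotation_tallies"),
                           ibs = reference_table("goose_ibs_matrix")) {
  stopifnot(all(c("n_snp", "n_ti", "n_tv", "n_het") %in% names(variants)))
  m <- as.matrix(ibs)
  if (!isSymmetric(unname(m))) stop("IBS matrix must be symmetric")
  list(mean_snp = mean(variants$n_snp),
       mean_het = mean(variants$n_het),
       max_het = max(variants$n_het),
       mean_titv = mean(variants$n_ti / variants$n_tv),
       mean_intergenic = mean(tallies$intergenic),
       mean_intronic = mean(tallies$intronic),
       syn_nonsyn_ratio = mean(tallies$synonymous) /
         mean(tallies$non_synonymous),
       mean_ibs = mean(m))
}
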