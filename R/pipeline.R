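#' Pipeline configuration
#'
#' Bundles every stage's parameters plus stage toggles into one
#' serializable object. The effective configuration of a run is echoed
#' verbatim (as JSON) into the output directory so any stage can be
#' re-run.
#'
#' @param sim a [sweep_sim_config()], or `NULL` when `vcf` is given.
#' @param vcf optional input VCF path (phased, with INFO/AA) used instead
#'   of the simulator.
#' @param filter a [filter_config()].
#' @param run_scan,run_summaries stage toggles.
#' @param n_bins,ihs_threshold,min_ehh,sides scan parameters (see
#'   [standardize_ihs()], [extract_candidates()], [ihs_scan()]).
#' @param roh_params named list forwarded to [detect_roh()].
#' @param ld_params named list forwarded to [ld_decay()].
#' @param gff optional GFF3 path for candidate annotation.
#' @param out_dir output directory.
#' @param seed integer seed for the run.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sweep_sim_config(), vcf = NULL,
                            filter = filter_config(),
                            run_scan = TRUE, run_summaries = TRUE,
                            n_bins = 20, ihs_threshold = 2, min_ehh = 0.05,
                            sides = "both", roh_params = list(),
                            ld_params = list(max_het = 1, max_miss = 0.3),
                            gff = NULL, out_dir = tempfile("ihsscan_run_"),
                            seed = 1L) {
  structure(list(sim = sim, vcf = vcf, filter = filter,
                 run_scan = isTRUE(run_scan),
                 run_summaries = isTRUE(run_summaries), n_bins = n_bins,
                 ihs_threshold = ihs_threshold, min_ehh = min_ehh,
                 sides = sides, roh_params = roh_params,
                 ld_params = ld_params, gff = gff, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration back from its JSON echo
#'
#' Inverse of the `config.json` echo written by [run_pipeline()], so any
#' run can be reproduced from its output directory alone.
#'
#' @param path path to a JSON file written from a [pipeline_config()].
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  sim <- if (is.null(j$sim)) NULL else {
    j$sim$sweep_site_bp <- j$sim$sweep_site_bp %||% NA
    j$sim$sweep_start_freq <- j$sim$sweep_start_freq %||% NA
    j$sim$sweep_target_freq <- j$sim$sweep_target_freq %||% NA
    do.call(sweep_sim_config, j$sim)
  }
  filter <- do.call(filter_config, j$filter)
  # NULL fields serialize as empty lists; normalize them back
  drop_empty <- function(x) if (length(x) == 0) NULL else x
  pipeline_config(sim = sim, vcf = drop_empty(j$vcf), filter = filter,
                  run_scan = j$run_scan, run_summaries = j$run_summaries,
                  n_bins = j$n_bins, ihs_threshold = j$ihs_threshold,
                  min_ehh = j$min_ehh, sides = j$sides,
                  roh_params = as.list(j$roh_params),
                  ld_params = as.list(j$ld_params), gff = drop_empty(j$gff),
                  out_dir = j$out_dir, seed = j$seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_tsv <- function(x, path, row_names = FALSE) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = row_names, col.names = TRUE)
  path
}

#' Run the full scan pipeline
#'
#' Executes simulate (or load) -> scan-level QC -> summaries -> iHS scan ->
#' candidate extraction/annotation, writing TSV/BED/JSON outputs plus a
#' manifest (seed, configuration echo, package/R versions, per-stage record
#' counts, md5 hashes of every output) and a human-readable Markdown
#' report. With a fixed seed and configuration the text outputs are
#' byte-identical across runs. Any stage error aborts with the stage name.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed,
                   r_version = R.version.string,
                   package_version = as.character(
                     utils::packageVersion("ihsscan")),
                   stages = list(), warnings = list())
  outputs <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # --- input panel ------------------------------------------------------
  panel <- stage("input", {
    if (!is.null(config$vcf)) read_phased_vcf(config$vcf)
    else simulate_panel(config$sim)
  })
  manifest$stages$input <- list(n_sites = ncol(panel$alleles),
                                n_samples = length(panel$sample_ids),
                                sweep_freq = attr(panel, "sweep_freq"))
  vcf_out <- file.path(config$out_dir, "panel.vcf")
  write_phased_vcf(panel, vcf_out)
  outputs <- c(outputs, vcf_out)

  # --- scan-level QC ----------------------------------------------------
  tbl <- as_site_table(panel)
  qc <- stage("scan_qc", apply_scan_qc(tbl, config$filter))
  ledger_path <- file.path(config$out_dir, "qc_ledger.tsv")
  write_tsv(qc, ledger_path)
  outputs <- c(outputs, ledger_path)
  keep <- qc$pass
  manifest$stages$scan_qc <- list(n_in = nrow(qc), n_pass = sum(keep))
  panel_qc <- panel_subset(panel, keep)

  results <- list(panel = panel, qc = qc)

  # --- summaries --------------------------------------------------------
  if (config$run_summaries) {
    res <- stage("summaries", {
      tq <- as_site_table(panel_qc)
      ind <- individual_stats(tq)
      ibs <- ibs_distance_matrix(tq)
      div <- diversity_stats(tq)
      roh <- do.call(detect_roh, c(list(tq), config$roh_params))
      ld <- do.call(ld_decay, c(list(panel_qc), config$ld_params))
      list(individual = ind, ibs = ibs, diversity = div, roh = roh, ld = ld)
    })
    p1 <- write_tsv(res$individual,
                    file.path(config$out_dir, "individual_stats.tsv"))
    p2 <- write_tsv(as.data.frame(res$ibs),
                    file.path(config$out_dir, "ibs_matrix.tsv"),
                    row_names = TRUE)
    p3 <- write_tsv(res$diversity$per_site,
                    file.path(config$out_dir, "diversity_per_site.tsv"))
    p4 <- write_tsv(res$ld, file.path(config$out_dir, "ld_decay.tsv"))
    roh_bed <- file.path(config$out_dir, "roh.bed")
    writeLines(if (nrow(res$roh))
      sprintf("%s\t%d\t%d\t%s\t%d", res$roh$chrom, res$roh$start_bp - 1L,
              res$roh$end_bp, res$roh$sample_id, res$roh$n_snps)
      else character(0), roh_bed)
    outputs <- c(outputs, p1, p2, p3, p4, roh_bed)
    manifest$stages$summaries <- list(n_samples = nrow(res$individual),
                                      n_roh = nrow(res$roh),
                                      n_ld_bins = nrow(res$ld))
    results$summaries <- res
  }

  # --- iHS scan ---------------------------------------------------------
  if (config$run_scan) {
    scan <- stage("scan", {
      rec <- ihs_scan(panel_qc, min_ehh = config$min_ehh,
                      min_maf = config$filter$min_maf, sides = config$sides)
      rec <- standardize_ihs(rec, n_bins = config$n_bins)
      rec <- significance(rec)
      cand <- extract_candidates(rec, threshold = config$ihs_threshold)
      if (!is.null(config$gff)) cand <- annotate_candidates(cand, config$gff)
      list(records = rec, candidates = cand)
    })
    p5 <- write_tsv(scan$records, file.path(config$out_dir, "ihs_records.tsv"))
    bed <- file.path(config$out_dir, "candidates.bed")
    writeLines(if (nrow(scan$candidates))
      sprintf("%s\t%d\t%d\t%.3f\t%d", scan$candidates$chrom,
              scan$candidates$start_bp - 1L, scan$candidates$end_bp,
              scan$candidates$peak_ihs, scan$candidates$n_snps)
      else character(0), bed)
    bins <- attr(scan$records, "bin_stats")
    binp <- file.path(config$out_dir, "bin_stats.json")
    jsonlite::write_json(bins, binp, dataframe = "rows", digits = NA)
    outputs <- c(outputs, p5, bed, binp)
    manifest$stages$scan <- list(n_scored = nrow(scan$records),
                                 n_candidates = nrow(scan$candidates),
                                 bin_merges = attr(scan$records, "merges"))
    results$scan <- scan
  }

  # --- manifest + report ------------------------------------------------
  cfg_path <- file.path(config$out_dir, "config.json")
  jsonlite::write_json(config, cfg_path, auto_unbox = TRUE, force = TRUE,
                       digits = NA)
  manifest$outputs <- as.list(tools::md5sum(outputs))
  man_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA)

  report <- c("# ihsscan pipeline report", "",
              sprintf("- seed: %d", config$seed),
              sprintf("- input sites: %d, samples: %d",
                      ncol(panel$alleles), length(panel$sample_ids)),
              sprintf("- QC pass: %d / %d", sum(keep), nrow(qc)))
  if (config$run_scan)
    report <- c(report,
                sprintf("- scored SNPs: %d", nrow(results$scan$records)),
                sprintf("- candidate regions (|iHS| > %g): %d",
                        config$ihs_threshold,
                        nrow(results$scan$candidates)))
  writeLines(report, file.path(config$out_dir, "report.md"))

  results$manifest <- manifest
  invisible(results)
}

#' Render publication-shaped summary tables
#'
#' Formats per-individual variant statistics and a pairwise distance matrix
#' the way resequencing papers print them: a per-individual table
#' (SNP, Ti, Tv, Ti/Tv to 2 decimals, He = heterozygous count,
#' Ho = homozygous count) with an "Average" row, an annotation-tally table
#' with an "Average" row, and a symmetric distance matrix to 2 decimals
#' with a blank diagonal. The Average Ti/Tv cell is the mean of the
#' per-individual ratios. Counts are rendered as rounded integers; full
#' precision stays in the underlying data.
#'
#' @param ind_stats data frame from [individual_stats()] (or any frame with
#'   `sample_id`, `n_snp`, `n_ti`, `n_tv`, `n_het`, `n_hom` and optional
#'   `ann_*` columns).
#' @param ibs optional numeric distance matrix.
#' @return list of character data frames: `variants`, `annotations` (when
#'   tally columns exist), `distances` (when `ibs` given).
#' @export
render_tables <- function(ind_stats, ibs = NULL) {
  ratio <- ind_stats$n_ti / ind_stats$n_tv
  t1 <- data.frame(Item = ind_stats$sample_id,
                   SNP = ind_stats$n_snp, Ti = ind_stats$n_ti,
                   Tv = ind_stats$n_tv,
                   `Ti/Tv` = sprintf("%.2f", ratio),
                   He = ind_stats$n_het, Ho = ind_stats$n_hom,
                   check.names = FALSE, stringsAsFactors = FALSE)
  avg <- data.frame(Item = "Average",
                    SNP = round(mean(ind_stats$n_snp)),
                    Ti = round(mean(ind_stats$n_ti)),
                    Tv = round(mean(ind_stats$n_tv)),
                    `Ti/Tv` = sprintf("%.2f", mean(ratio)),
                    He = round(mean(ind_stats$n_het)),
                    Ho = round(mean(ind_stats$n_hom)),
                    check.names = FALSE, stringsAsFactors = FALSE)
  out <- list(variants = rbind(t1, avg))

  ann_cols <- grep("^ann_", names(ind_stats), value = TRUE)
  if (length(ann_cols)) {
    t2 <- ind_stats[, c("sample_id", ann_cols)]
    names(t2) <- c("Item", sub("^ann_", "", ann_cols))
    avg2 <- c(Item = "Average",
              as.list(round(colMeans(ind_stats[, ann_cols, drop = FALSE]))))
    names(avg2) <- names(t2)
    out$annotations <- rbind(t2, as.data.frame(avg2,
                                               stringsAsFactors = FALSE))
  }
  if (!is.null(ibs)) {
    m <- as.matrix(ibs)
    fm <- matrix(sprintf("%.2f", m), nrow = nrow(m),
                 dimnames = dimnames(m))
    diag(fm) <- ""
    out$distances <- as.data.frame(fm, stringsAsFactors = FALSE)
  }
  out
}
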