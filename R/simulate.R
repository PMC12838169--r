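#' Configuration for the Wright-Fisher sweep simulator
#'
#' Parameters of a forward-in-time diploid Wright-Fisher simulation with
#' per-generation mutation on a fixed site grid, Poisson crossover
#' recombination, and an optional additive selective sweep. The defaults
#' describe a desk-scale stand-in for a small resequenced waterfowl cohort
#' (15 diploids, as in typical conservation-flock studies); rates are
#' scaled so that a few hundred generations reach mutation-drift
#' equilibrium on a megabase-scale chromosome.
#'
#' @param n_diploids number of diploid individuals (>= 2).
#' @param n_sites number of grid sites available for mutation (>= 2).
#' @param chrom_length_bp chromosome length in bp.
#' @param mu per-site, per-gamete, per-generation mutation probability.
#' @param rho per-bp, per-meiosis crossover probability.
#' @param n_generations generations to simulate.
#' @param sel_coeff additive selection coefficient s >= 0; fitnesses at the
#'   sweep site are 1, 1+s, 1+2s by derived dosage.
#' @param sweep_site_bp 1-based position of the selected site, or `NA` for
#'   a fully neutral run.
#' @param sweep_start_freq initial derived-allele frequency at the sweep
#'   site, in (0, 1); rounded to at least one copy.
#' @param sweep_intro_gen generation at which the sweep allele is seeded
#'   (0 = before the first generation). Earlier generations are neutral
#'   burn-in that builds standing variation.
#' @param sweep_target_freq optional frequency at which the run stops early
#'   (e.g. 0.9 to obtain "swept" panels); `NA` runs all generations.
#' @param condition_on_sweep if `TRUE`, a lost sweep allele is immediately
#'   re-seeded as a fresh single copy, i.e. the run is conditioned on
#'   establishment of the sweep from a single origin.
#' @param seed integer seed; identical config + seed gives bit-identical
#'   output.
#'
#' @return an object of class `sweep_sim_config`.
#' @export
sweep_sim_config <- function(n_diploids = 15, n_sites = 5000,
                             chrom_length_bp = 5e6, mu = 1.2e-4,
                             rho = 5e-7, n_generations = 10 * n_diploids,
                             sel_coeff = 0, sweep_site_bp = NA,
                             sweep_start_freq = NA,
                             sweep_intro_gen = 0,
                             sweep_target_freq = NA,
                             condition_on_sweep = FALSE, seed = 1L) {
  cfg <- list(n_diploids = as.integer(n_diploids),
              n_sites = as.integer(n_sites),
              chrom_length_bp = as.numeric(chrom_length_bp),
              mu = mu, rho = rho,
              n_generations = as.integer(n_generations),
              sel_coeff = sel_coeff,
              sweep_site_bp = sweep_site_bp,
              sweep_start_freq = sweep_start_freq,
              sweep_intro_gen = as.integer(sweep_intro_gen),
              sweep_target_freq = sweep_target_freq,
              condition_on_sweep = isTRUE(condition_on_sweep),
              seed = as.integer(seed))
  if (cfg$n_diploids < 2L) stop("n_diploids must be >= 2")
  if (cfg$n_sites < 2L) stop("n_sites must be >= 2")
  if (cfg$mu < 0 || cfg$rho < 0) stop("rates must be nonnegative")
  if (cfg$sel_coeff < 0) stop("sel_coeff must be >= 0")
  if (!is.na(cfg$sweep_site_bp)) {
    if (cfg$sweep_site_bp < 1 || cfg$sweep_site_bp > cfg$chrom_length_bp)
      stop("sweep site lies outside the chromosome (1..",
           format(cfg$chrom_length_bp), " bp)")
    if (is.na(cfg$sweep_start_freq)) cfg$sweep_start_freq <- 1 / (2 * cfg$n_diploids)
    if (cfg$sweep_start_freq <= 0 || cfg$sweep_start_freq >= 1)
      stop("sweep_start_freq must lie in (0, 1)")
    if (cfg$sweep_intro_gen < 0 || cfg$sweep_intro_gen >= cfg$n_generations)
      stop("sweep_intro_gen must lie in [0, n_generations)")
  }
  class(cfg) <- "sweep_sim_config"
  cfg
}

#' Simulate a phased haplotype panel under Wright-Fisher dynamics
#'
#' Runs a forward diploid Wright-Fisher simulation from a monomorphic
#' (all-ancestral) start. Mutations fall on a fixed site grid; at any
#' moment each segregating derived allele traces back to a single mutation
#' event and back-mutation never occurs, so the 0/1 coding is unambiguously
#' polarized. Crossovers per meiosis are Poisson(`rho * chrom_length_bp`)
#' with uniform breakpoints. If a sweep site is configured, its derived
#' allele is seeded at `sweep_start_freq` at generation `sweep_intro_gen`
#' and experiences additive selection thereafter.
#'
#' The returned panel is restricted to segregating sites. Attributes record
#' the realized derived-allele frequency at the sweep site
#' (`sweep_freq`), its position if still segregating (`sweep_site_bp`), and
#' the number of generations actually run (`generations_run`).
#'
#' @param config a [sweep_sim_config()].
#' @return a [haplotype_panel()].
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sweep_sim_config"))
  set.seed(config$seed)
  M <- 2L * config$n_diploids

  positions <- sort(sample.int(config$chrom_length_bp, config$n_sites))
  sweep_idx <- -1L
  if (!is.na(config$sweep_site_bp)) {
    # reserve the exact sweep position on the grid
    sp <- as.integer(config$sweep_site_bp)
    if (!(sp %in% positions)) {
      positions <- sort(unique(c(positions, sp)))
      if (length(positions) > config$n_sites)
        positions <- positions[-which.max(abs(positions - sp) *
                                            (positions != sp))]
      positions <- sort(positions)
    }
    sweep_idx <- match(sp, positions) - 1L   # 0-based for C++
  }
  S <- length(positions)
  H <- matrix(0L, nrow = S, ncol = M)

  gens_total <- 0L
  if (sweep_idx >= 0L && config$sweep_intro_gen > 0L) {
    burn <- .wf_generations(H, as.numeric(positions), config$chrom_length_bp,
                            config$sweep_intro_gen, config$mu, config$rho,
                            sweep_idx, 0, -1, FALSE)
    H <- burn$H
    gens_total <- burn$generations_run
  }

  if (sweep_idx >= 0L) {
    n_copies <- max(1L, round(config$sweep_start_freq * M))
    carriers <- sample.int(M, n_copies)
    H[sweep_idx + 1L, ] <- 0L
    H[sweep_idx + 1L, carriers] <- 1L
    target <- if (is.na(config$sweep_target_freq)) -1 else config$sweep_target_freq
    res <- .wf_generations(H, as.numeric(positions), config$chrom_length_bp,
                           config$n_generations - config$sweep_intro_gen,
                           config$mu, config$rho, sweep_idx,
                           config$sel_coeff, target,
                           config$condition_on_sweep)
  } else {
    res <- .wf_generations(H, as.numeric(positions), config$chrom_length_bp,
                           config$n_generations, config$mu, config$rho,
                           -1L, 0, -1, FALSE)
  }
  H <- res$H
  gens_total <- gens_total + res$generations_run

  cnt <- rowSums(H)
  seg <- cnt > 0L & cnt < M
  if (!any(seg))
    stop("no segregating sites at the end of the run; ",
         "raise mu or n_generations")
  keep <- which(seg)
  alleles <- t(H[keep, , drop = FALSE])
  pos_seg <- positions[keep]

  # cosmetic REF/ALT bases: transition-biased so Ti/Tv looks vertebrate-like
  S2 <- length(keep)
  ref <- sample(c("A", "C", "G", "T"), S2, replace = TRUE)
  ti_partner <- c(A = "G", G = "A", C = "T", T = "C")
  tv_pool <- list(A = c("C", "T"), G = c("C", "T"),
                  C = c("A", "G"), T = c("A", "G"))
  is_ti <- stats::runif(S2) < 0.7
  alt <- ifelse(is_ti, ti_partner[ref],
                vapply(tv_pool[ref], function(p) sample(p, 1L), ""))
  anc_is_ref <- stats::runif(S2) < 0.8

  panel <- haplotype_panel(alleles, pos_seg, chrom_id = "chr1",
                           sample_ids = sprintf("S%02d",
                                                seq_len(config$n_diploids)),
                           ref = ref, alt = alt, anc_is_ref = anc_is_ref)
  attr(panel, "sweep_freq") <- res$sweep_freq
  attr(panel, "sweep_site_bp") <-
    if (sweep_idx >= 0L && seg[sweep_idx + 1L]) positions[sweep_idx + 1L] else NA
  attr(panel, "generations_run") <- gens_total
  attr(panel, "chrom_length_bp") <- config$chrom_length_bp
  panel
}
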