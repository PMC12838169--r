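#' Extended haplotype homozygosity around a core SNP
#'
#' For the haplotypes carrying one allele at the core site, EHH at an
#' offset x is the probability that two randomly drawn carriers are
#' identical over every marker between the core and x:
#' `EHH(x) = sum_h C(k_h, 2) / C(n_c, 2)` with `k_h` the sizes of the
#' identical extended-haplotype classes among the `n_c` carriers.
#' Haplotypes are compared as exact 0/1 strings (no mismatch allowance).
#' The walk proceeds marker by marker, separately left and right, and stops
#' at the first marker where EHH drops below `min_ehh` (that marker is kept
#' as the final node) or at the chromosome end; which happened is recorded
#' per direction.
#'
#' @param panel a [haplotype_panel()].
#' @param core 1-based site index of the core SNP (must be polymorphic).
#' @param allele `"A"` (ancestral, 0-coded) or `"D"` (derived, 1-coded).
#' @param min_ehh truncation threshold for the outward walk.
#' @return an `ehh_curve`: list with `offsets_bp` (signed, 0 at the core),
#'   `ehh` (EHH at each offset, 1 at offset 0), `truncated_left`,
#'   `truncated_right` (`TRUE` = stopped by the threshold, `FALSE` =
#'   reached the chromosome end), `n_carriers`, `core`, `allele`.
#' @export
compute_ehh <- function(panel, core, allele = c("D", "A"), min_ehh = 0.05) {
  stopifnot(inherits(panel, "haplotype_panel"))
  allele <- match.arg(allele)
  a <- if (allele == "D") 1L else 0L
  carriers <- which(panel$alleles[, core] == a)
  if (length(carriers) < 2L)
    stop("fewer than 2 carriers of allele ", allele, " at site ", core)
  A <- t(panel$alleles)                # sites x haplotypes for the kernel
  left <- .ehh_side(A, carriers - 1L, core - 1L, -1L, min_ehh)
  right <- .ehh_side(A, carriers - 1L, core - 1L, 1L, min_ehh)
  pos <- panel$positions_bp
  offsets <- c(rev(pos[left$sites] - pos[core]), 0L,
               pos[right$sites] - pos[core])
  ehh <- c(rev(left$ehh), 1, right$ehh)
  structure(list(offsets_bp = offsets, ehh = ehh,
                 truncated_left = left$truncated,
                 truncated_right = right$truncated,
                 n_carriers = length(carriers),
                 core = core, allele = allele, min_ehh = min_ehh),
            class = "ehh_curve")
}

#' Integrate an EHH curve into iHH
#'
#' Trapezoidal integration of EHH over physical distance (bp), summed over
#' the left and right flanks (or one flank with `sides = "right"`, the
#' literal one-sided reading of the defining integral). In each direction
#' the integral runs from the core (EHH = 1 at offset 0) to the curve's
#' final node, which is either the first marker below the truncation
#' threshold or the last marker on the chromosome.
#'
#' @param curve an `ehh_curve` from [compute_ehh()].
#' @param sides `"both"` (default) or `"right"`.
#' @return iHH in bp units; a single-point curve integrates to 0 with a
#'   warning.
#' @export
integrate_ihh <- function(curve, sides = c("both", "right")) {
  stopifnot(inherits(curve, "ehh_curve"))
  sides <- match.arg(sides)
  off <- as.numeric(curve$offsets_bp)
  e <- curve$ehh
  if (length(off) < 2L) {
    warning("single-point EHH curve: zero-width integral")
    return(0)
  }
  trapz <- function(x, y) {
    if (length(x) < 2L) return(0)
    sum(diff(x) * (utils::head(y, -1L) + utils::tail(y, -1L)) / 2)
  }
  right <- off >= 0
  ihh <- trapz(off[right], e[right])
  if (sides == "both") {
    left <- off <= 0
    ihh <- ihh + trapz(-rev(off[left]), rev(e[left]))
  }
  ihh
}

#' Unstandardized integrated haplotype score
#'
#' Natural log of the ancestral-to-derived iHH ratio; positive when
#' haplotypes around the ancestral allele are longer.
#'
#' @param ihh_a,ihh_d integrated haplotype homozygosity for the ancestral
#'   and derived alleles (both must be positive).
#' @return `ln(ihh_a / ihh_d)` (computed as a log difference, so swapping
#'   the arguments negates the result exactly).
#' @export
unstandardized_ihs <- function(ihh_a, ihh_d) {
  if (any(ihh_a <= 0) || any(ihh_d <= 0))
    stop("iHH values must be positive")
  log(ihh_a) - log(ihh_d)
}
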