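# Coverage-derived relative copy number, the D-loop / 7S coverage
# comparison, and closed-form calculators for the blood-admixture
# threshold and liver replication counts.

#' Relative mtDNA copy number from a coverage profile
#'
#' The capture-enrichment coverage of the mtDNA genome scales with the
#' cellular mtDNA copy number; mean depth times a calibration ratio
#' (default 1/150) converts the relative value to an absolute copy
#' number per cell. The absolute scale is as calibrated elsewhere and
#' only ratios are meaningful without it.
#'
#' @param coverage per-position depth vector.
#' @param correction_ratio depth-to-copies calibration (1/150).
#' @return copy-number estimate.
#' @export
relative_copy_number <- function(coverage, correction_ratio = 1 / 150) {
  if (!length(coverage)) stop("empty coverage profile")
  mean(coverage) * correction_ratio
}

#' D-loop vs rest-of-genome coverage ratio
#'
#' Per sample, the ratio of mean depth in the D-loop (where 7S DNA would
#' add template) to mean depth elsewhere; a cohort-level two-sided
#' Wilcoxon test of the per-sample ratios against 1 asks whether 7S DNA
#' inflates D-loop coverage.
#'
#' @param coverage per-position depth vector (single sample), or a
#'   matrix with one column per sample.
#' @param map a `region_map`.
#' @return for a vector: the ratio. For a matrix: list `ratios`, `p`
#'   (two-sided Wilcoxon signed-rank of ratios vs 1).
#' @export
dloop_coverage_ratio <- function(coverage, map = region_map()) {
  one <- function(cv) {
    if (length(cv) < max(map$dloop)) stop("profile shorter than the D-loop")
    dl <- mean(cv[map$dloop])
    rest <- mean(cv[-map$dloop])
    if (rest == 0) stop("empty region")
    dl / rest
  }
  if (is.matrix(coverage)) {
    ratios <- apply(coverage, 2L, one)
    list(ratios = ratios,
         p = stats::wilcox.test(ratios, mu = 1, exact = FALSE)$p.value)
  } else one(coverage)
}

#' Minimum blood MAF that could masquerade as a liver heteroplasmy
#'
#' A liver autopsy sample contains blood; a blood-only heteroplasmy is
#' diluted by the ratio of liver-derived to blood-derived mitochondrial
#' genomes, R = cell_ratio x copy_factor (with ~1.8 liver cells per
#' blood cell and a 5x higher mtDNA copy number in liver, R = 9). To
#' reach the liver calling threshold the blood MAF must be at least
#' threshold = liver_maf_min x R (2.5% x 9 = 22.5%); values above 100%
#' are capped and flagged impossible.
#'
#' @param cell_ratio liver:blood cell ratio in the autopsy sample (1.8).
#' @param copy_factor liver:blood mtDNA copy-number ratio per cell (5).
#' @param liver_maf_min liver calling threshold (0.025).
#' @return list: `genome_ratio`, `threshold` (fraction, capped at 1),
#'   `impossible`.
#' @export
blood_admixture_threshold <- function(cell_ratio = 1.8, copy_factor = 5,
                                      liver_maf_min = 0.025) {
  if (cell_ratio <= 0 || copy_factor <= 0 || liver_maf_min <= 0)
    stop("inputs must be positive")
  R <- cell_ratio * copy_factor
  th <- liver_maf_min * R
  list(genome_ratio = R, threshold = min(th, 1), impossible = th > 1)
}

#' Cell doublings needed to reach a cell count
#'
#' `ceiling(log2(n_cells))`: e.g. the ~3.61e11 cells of an adult liver
#' require 39 doublings from a single founder cell.
#'
#' @param n_cells target number of cells (>= 1).
#' @return integer number of doublings.
#' @export
replications_to_cells <- function(n_cells) {
  if (any(n_cells < 1)) stop("n_cells must be >= 1")
  as.integer(ceiling(log2(n_cells)))
}

#' Surviving original mtDNA molecules under relaxed replication turnover
#'
#' With exponential decay at the given half-life, the expected number of
#' original molecules after `horizon_days` is
#' `copy_number * 2^(-horizon/half_life)`; "complete replacement" means
#' fewer than one survivor (e.g. a 30-day half-life replaces all 2,500
#' copies of a cell within a year).
#'
#' @param half_life_days mtDNA half-life in days.
#' @param copy_number mtDNA copies per cell.
#' @param horizon_days elapsed time in days.
#' @return list: `survivors`, `complete_replacement`.
#' @export
mtdna_turnover_cycles <- function(half_life_days, copy_number, horizon_days) {
  if (half_life_days <= 0 || copy_number <= 0 || horizon_days < 0)
    stop("inputs must be positive (horizon may be zero)")
  s <- copy_number * 2^(-horizon_days / half_life_days)
  list(survivors = s, complete_replacement = s < 1)
}
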