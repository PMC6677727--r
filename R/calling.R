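# Heteroplasmy calling: MAF computation relative to the blood major
# allele, a binomial-tail quality score, the filter cascade, sample-level
# QC and cross-sample contamination screens.

#' Default heteroplasmy filter configuration
#'
#' Thresholds of the calling filter cascade. All "at least" thresholds
#' are inclusive.
#'
#' @param maf_min minimum minor allele frequency on each strand (0.025).
#' @param depth_min minimum sequencing depth at a site (500).
#' @param minor_reads_min_per_strand minimum reads supporting the minor
#'   allele on each strand (10).
#' @param quality_min_per_strand minimum per-strand quality score (10);
#'   waived at common heteroplasmic sites of the tissue.
#' @param coverage_band allowed site depth as a fraction of the sample
#'   mean depth, `c(low, high)` (0.2-2).
#' @param sample_low_coverage_max maximum tolerated fraction of the
#'   genome below `depth_min` before a sample (and its individual) is
#'   dropped; the comparison is strict ("more than").
#' @param common_sites named list of positions per tissue class at which
#'   the quality criterion is waived (defaults: liver 60, 72, 94, 185,
#'   189, 203, 11126, 16093, 16126; blood 12705).
#' @param common_site_min_individuals minimum number of heteroplasmic
#'   individuals for [recompute_common_sites()] (5).
#' @param error_rate assumed per-base sequencing error rate for the
#'   quality score (0.001).
#' @param quality_cap cap for the quality score (999).
#' @param contamination thresholds of the pairwise screen: `min_frac_donor_major`
#'   (0.8), `min_mean_maf` (0.01), `min_frac_called` (0.6).
#' @param haplogroup_min_sites minimum number of minor alleles jointly
#'   explained by one other sample's consensus before an individual is
#'   dropped (5).
#' @return list of class `filter_config`.
#' @export
filter_config <- function(maf_min = 0.025,
                          depth_min = 500L,
                          minor_reads_min_per_strand = 10L,
                          quality_min_per_strand = 10,
                          coverage_band = c(0.2, 2.0),
                          sample_low_coverage_max = 0.02,
                          common_sites = list(
                            liver = c(60L, 72L, 94L, 185L, 189L, 203L,
                                      11126L, 16093L, 16126L),
                            blood = 12705L),
                          common_site_min_individuals = 5L,
                          error_rate = 0.001,
                          quality_cap = 999,
                          contamination = list(min_frac_donor_major = 0.8,
                                               min_mean_maf = 0.01,
                                               min_frac_called = 0.6),
                          haplogroup_min_sites = 5L) {
  stopifnot(maf_min > 0, maf_min < 0.5, depth_min > 0,
            minor_reads_min_per_strand > 0, quality_min_per_strand > 0,
            length(coverage_band) == 2L, coverage_band[1] < coverage_band[2],
            error_rate > 0, error_rate < 0.5)
  structure(as.list(environment()), class = "filter_config")
}

# tissue -> common-site class ("liver1"/"liver2" -> "liver")
tissue_class <- function(tissue) sub("[0-9]+$", "", tissue)

count_matrices <- function(counts) {
  miss <- setdiff(COUNT_COLS, names(counts))
  if (length(miss)) stop("missing count columns: ", paste(miss, collapse = ", "))
  fwd <- as.matrix(counts[paste0(BASES, "_fwd")])
  rev <- as.matrix(counts[paste0(BASES, "_rev")])
  storage.mode(fwd) <- "double"; storage.mode(rev) <- "double"
  colnames(fwd) <- BASES; colnames(rev) <- BASES
  list(fwd = fwd, rev = rev, tot = fwd + rev)
}

#' Consensus (overall major) allele per site of one sample
#'
#' @param counts strand-resolved count table (columns `pos`, `A_fwd` ...
#'   `T_rev`).
#' @return data.frame `pos`, `consensus`.
#' @export
consensus_alleles <- function(counts) {
  m <- count_matrices(counts)
  data.frame(pos = counts$pos,
             consensus = BASES[max.col(m$tot, ties.method = "first")],
             stringsAsFactors = FALSE)
}

#' Minor allele frequency relative to the blood major allele
#'
#' The minor allele at a site is the most frequent allele other than the
#' major allele observed in blood for the same individual; its frequency
#' is computed overall and per strand. Because the orientation is the
#' *blood* major, MAF values above 0.5 are legal and flag a consensus
#' flip (the tissue consensus differs from blood). Ties between two
#' candidate minor alleles break toward the higher combined-strand count,
#' then alphabetically, and are flagged.
#'
#' Vectorised: one row per site.
#'
#' @param counts strand-resolved count table.
#' @param blood_major character vector of blood major alleles (recycled).
#' @return data.frame: `pos`, `major` (blood), `minor`, `maf`, `maf_fwd`,
#'   `maf_rev`, `minor_fwd`, `minor_rev`, `depth`, `tie`,
#'   `consensus_flip`.
#' @export
compute_maf <- function(counts, blood_major) {
  m <- count_matrices(counts)
  n <- nrow(m$tot)
  blood_major <- rep_len(toupper(blood_major), n)
  if (any(!blood_major %in% BASES)) stop("blood_major must be A/C/G/T")
  depth <- rowSums(m$tot)
  if (any(depth == 0)) stop("zero depth at position(s) ",
                            paste(utils::head(counts$pos[depth == 0], 5), collapse = ", "))
  majidx <- match(blood_major, BASES)
  masked <- m$tot
  masked[cbind(seq_len(n), majidx)] <- -1
  minidx <- max.col(masked, ties.method = "first")
  rowmax <- masked[cbind(seq_len(n), minidx)]
  tie <- rowSums(masked == rowmax) > 1L
  sel <- cbind(seq_len(n), minidx)
  minor_cnt <- m$tot[sel]
  fwd_depth <- rowSums(m$fwd); rev_depth <- rowSums(m$rev)
  data.frame(
    pos = counts$pos,
    major = blood_major,
    minor = BASES[minidx],
    maf = minor_cnt / depth,
    maf_fwd = ifelse(fwd_depth > 0, m$fwd[sel] / fwd_depth, 0),
    maf_rev = ifelse(rev_depth > 0, m$rev[sel] / rev_depth, 0),
    minor_fwd = m$fwd[sel],
    minor_rev = m$rev[sel],
    fwd_depth = fwd_depth,
    rev_depth = rev_depth,
    depth = depth,
    tie = tie,
    consensus_flip = minor_cnt / depth > 0.5,
    stringsAsFactors = FALSE
  )
}

#' Per-strand binomial-tail quality score
#'
#' Substitute for an external heteroplasmic quality score: the score is
#' `-10 log10 P(X >= k)` with `X ~ Binomial(strand depth, error_rate)`
#' and `k` the minor-allele reads on that strand -- the Phred-scaled
#' probability that sequencing error alone produces at least the observed
#' minor support. A minor count of 0 scores 0. Scores are capped.
#' If the input table carries `quality_fwd` / `quality_rev` columns (an
#' externally computed score), those take precedence in [call_sample()].
#'
#' @param minor_reads minor-allele read counts on the strand.
#' @param strand_depth total reads on the strand.
#' @param error_rate per-base error probability (in (0, 0.5)).
#' @param cap maximum score.
#' @return numeric score vector.
#' @export
quality_score <- function(minor_reads, strand_depth, error_rate = 0.001,
                          cap = 999) {
  stopifnot(error_rate > 0, error_rate < 0.5)
  logp <- stats::pbinom(minor_reads - 1, strand_depth, error_rate,
                        lower.tail = FALSE, log.p = TRUE)
  score <- -10 / log(10) * logp
  score[minor_reads <= 0] <- 0
  pmin(score, cap)
}

#' Apply the heteroplasmy filter cascade to one sample
#'
#' A site passes iff all of: per-strand MAF >= `maf_min`; depth >=
#' `depth_min`; minor reads >= `minor_reads_min_per_strand` on each
#' strand; per-strand quality >= `quality_min_per_strand` *or* the
#' position is a common heteroplasmic site for the tissue; the position
#' is not in an excluded region; the site depth lies within
#' `coverage_band` of the sample mean depth. The pass decision is a pure
#' conjunction; every failed criterion is recorded in `reasons`.
#'
#' @param counts strand-resolved count table for the sample; optional
#'   `quality_fwd`/`quality_rev` columns override the internal score.
#' @param blood_major blood major allele per row.
#' @param tissue tissue of the sample ("blood", "liver1", "liver2").
#' @param mean_depth mean sequencing depth of the sample across the
#'   genome (for the coverage band).
#' @param config a [filter_config()].
#' @param map a `region_map` (or NULL to skip region exclusion).
#' @return data.frame of per-site calls: MAF fields plus `qual_fwd`,
#'   `qual_rev`, `pass`, `reasons` (comma-separated, "" when passing).
#' @export
call_sample <- function(counts, blood_major, tissue, mean_depth,
                        config = filter_config(), map = region_map()) {
  maf <- compute_maf(counts, blood_major)
  if (all(c("quality_fwd", "quality_rev") %in% names(counts))) {
    qf <- counts$quality_fwd; qr <- counts$quality_rev
  } else {
    qf <- quality_score(maf$minor_fwd, maf$fwd_depth, config$error_rate,
                        config$quality_cap)
    qr <- quality_score(maf$minor_rev, maf$rev_depth, config$error_rate,
                        config$quality_cap)
  }
  common <- config$common_sites[[tissue_class(tissue)]]
  if (is.null(common)) common <- integer()
  is_common <- maf$pos %in% common
  excluded <- if (is.null(map)) rep(FALSE, nrow(maf)) else maf$pos %in% map$excluded

  fail <- list(
    low_maf = !(maf$maf_fwd >= config$maf_min & maf$maf_rev >= config$maf_min),
    low_depth = !(maf$depth >= config$depth_min),
    strand_support = !(maf$minor_fwd >= config$minor_reads_min_per_strand &
                         maf$minor_rev >= config$minor_reads_min_per_strand),
    low_quality = !(is_common |
                      (qf >= config$quality_min_per_strand &
                         qr >= config$quality_min_per_strand)),
    excluded_region = excluded,
    coverage_band = !(maf$depth >= config$coverage_band[1] * mean_depth &
                        maf$depth <= config$coverage_band[2] * mean_depth)
  )
  fm <- do.call(cbind, fail)
  reasons <- apply(fm, 1L, function(r) paste(names(fail)[r], collapse = ","))
  out <- maf
  out$tissue <- tissue
  out$qual_fwd <- qf
  out$qual_rev <- qr
  out$common_site <- is_common
  out$pass <- !rowSums(fm)
  out$reasons <- reasons
  out
}

#' Call a single site
#'
#' Convenience wrapper around [call_sample()] for one site.
#'
#' @inheritParams call_sample
#' @return one-row call data.frame.
#' @export
call_site <- function(counts, blood_major, tissue, mean_depth,
                      config = filter_config(), map = region_map()) {
  stopifnot(nrow(counts) == 1L)
  call_sample(counts, blood_major, tissue, mean_depth, config, map)
}

#' Sample-level coverage QC
#'
#' A sample is dropped when more than `sample_low_coverage_max` (default
#' 2%) of the genome has depth below `depth_min`; the comparison is
#' strict, so exactly 2% is kept. Dropping a sample removes all samples
#' of its individual downstream.
#'
#' @param coverage per-position depth vector over the whole genome.
#' @param config a [filter_config()].
#' @param genome_length expected profile length (checked).
#' @return list: `keep` (logical), `frac_below`, `reason`.
#' @export
sample_qc <- function(coverage, config = filter_config(),
                      genome_length = length(coverage)) {
  if (length(coverage) != genome_length)
    stop("coverage profile length ", length(coverage),
         " does not match genome length ", genome_length)
  frac <- mean(coverage < config$depth_min)
  keep <- frac <= config$sample_low_coverage_max
  list(keep = keep, frac_below = frac,
       reason = if (keep) "" else "low_coverage_fraction")
}

#' Pairwise cross-sample contamination screen
#'
#' A recipient sample is flagged as contaminated by a donor iff all
#' three criteria hold: (1) at >= 80% of the sites where the two samples
#' have different consensus alleles, the recipient's minor allele equals
#' the donor's major allele; (2) the recipient's average MAF across
#' those sites is >= 1%; (3) >= 60% of recipient sites with any minor
#' allele observed were called heteroplasmic. With zero
#' differing-consensus sites the pair is clear (a contaminant requires
#' observable donor signal).
#'
#' @param recipient_counts,donor_counts strand-resolved count tables.
#' @param recipient_calls call table of the recipient ([call_sample()]).
#' @param config a [filter_config()] (`$contamination` thresholds).
#' @return list: `flagged`, `n_diff_sites`, `frac_donor_major`,
#'   `mean_maf`, `frac_called`.
#' @export
pairwise_contamination_screen <- function(recipient_counts, donor_counts,
                                          recipient_calls,
                                          config = filter_config()) {
  th <- config$contamination
  rc <- consensus_alleles(recipient_counts)
  dc <- consensus_alleles(donor_counts)
  shared <- intersect(rc$pos, dc$pos)
  rcons <- rc$consensus[match(shared, rc$pos)]
  dcons <- dc$consensus[match(shared, dc$pos)]
  diff_pos <- shared[rcons != dcons]

  # recipient minor allele relative to the recipient's own consensus
  rmaf <- compute_maf(recipient_counts[match(shared, recipient_counts$pos), ,
                                       drop = FALSE], rcons)
  if (length(diff_pos) == 0L) {
    return(list(flagged = FALSE, n_diff_sites = 0L,
                frac_donor_major = NA_real_, mean_maf = NA_real_,
                frac_called = NA_real_))
  }
  at_diff <- match(diff_pos, rmaf$pos)
  frac_dm <- mean(rmaf$minor[at_diff] == dcons[rcons != dcons])
  mean_maf <- mean(rmaf$maf[at_diff])

  has_minor <- rmaf$pos[rmaf$maf > 0]
  frac_called <- if (length(has_minor))
    mean(has_minor %in% recipient_calls$pos[recipient_calls$pass])
  else NA_real_

  flagged <- isTRUE(frac_dm >= th$min_frac_donor_major) &&
    isTRUE(mean_maf >= th$min_mean_maf) &&
    isTRUE(frac_called >= th$min_frac_called)
  list(flagged = flagged, n_diff_sites = length(diff_pos),
       frac_donor_major = frac_dm, mean_maf = mean_maf,
       frac_called = frac_called)
}

#' Haplogroup-excess contamination filter
#'
#' Drops an individual when five or more of its heteroplasmic minor
#' alleles jointly match the consensus alleles of any single other
#' cohort sample at positions where that sample's consensus differs from
#' the recipient's own consensus -- the signature of low-level
#' contamination from another haplogroup.
#'
#' @param calls passed calls of the individual (columns `pos`, `minor`).
#' @param own_consensus data.frame `pos`, `consensus` for the individual.
#' @param other_consensus named list of `pos`/`consensus` data.frames,
#'   one per other cohort sample.
#' @param min_sites threshold (default 5).
#' @return list: `keep`, `max_matching`, `best_donor`.
#' @export
haplogroup_excess_filter <- function(calls, own_consensus, other_consensus,
                                     min_sites = 5L) {
  calls <- calls[calls$pass %||% rep(TRUE, nrow(calls)), , drop = FALSE]
  if (nrow(calls) == 0L || length(other_consensus) == 0L)
    return(list(keep = TRUE, max_matching = 0L, best_donor = NA_character_))
  own <- own_consensus$consensus[match(calls$pos, own_consensus$pos)]
  matches <- vapply(other_consensus, function(d) {
    dc <- d$consensus[match(calls$pos, d$pos)]
    sum(!is.na(dc) & dc != own & dc == calls$minor, na.rm = TRUE)
  }, integer(1))
  mx <- max(matches)
  list(keep = mx < min_sites, max_matching = mx,
       best_donor = if (mx > 0) names(matches)[which.max(matches)] else NA_character_)
}

#' Recompute common heteroplasmic sites from a first calling pass
#'
#' Alternative to the fixed common-site lists: a site is commonly
#' heteroplasmic in a tissue class when at least
#' `config$common_site_min_individuals` individuals carry a passed call
#' there (calls from a first pass, typically made with quality filtering
#' in force).
#'
#' @param calls long call table with `individual`, `tissue`, `pos`,
#'   `pass`.
#' @param config a [filter_config()].
#' @return named list of position vectors per tissue class, suitable for
#'   the `common_sites` field of [filter_config()].
#' @export
recompute_common_sites <- function(calls, config = filter_config()) {
  passed <- calls[calls$pass, , drop = FALSE]
  cls <- tissue_class(passed$tissue)
  out <- lapply(split(passed, cls), function(d) {
    per_site <- tapply(d$individual, d$pos, function(x) length(unique(x)))
    as.integer(names(per_site)[per_site >= config$common_site_min_individuals])
  })
  out
}
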