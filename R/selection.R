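# hN/hS: non-synonymous vs synonymous heteroplasmy rates over the mtDNA
# protein-coding genes, with an NG86-style unweighted site count as the
# denominator and a permutation null that re-places the observed
# substitutions uniformly over the coding region.

#' Expected synonymous and non-synonymous site counts
#'
#' For every complete codon of every protein-coding gene, each codon
#' position contributes a synonymous fraction equal to (number of the 3
#' possible substitutions that preserve the amino acid) / 3 under the
#' vertebrate mitochondrial code. S_sites is the sum of the fractions,
#' N_sites the complement, so N_sites + S_sites = 3 x number of complete
#' codons (overlapping genes are counted once per gene). This is the
#' unweighted NG86 site count; no multiple-hit correction is applied,
#' which is exact at heteroplasmy densities of at most one change per
#' codon.
#'
#' @param genome a [mito_genome()].
#' @return list: `N_sites`, `S_sites`, `n_codons`.
#' @export
count_syn_nonsyn_sites <- function(genome = mito_genome()) {
  eff <- substitution_effects(genome)
  if (!nrow(eff)) return(list(N_sites = 0, S_sites = 0, n_codons = 0L))
  # per (gene, pos): 3 possible substitutions; synonymous fraction
  key <- paste(eff$gene, eff$pos)
  syn_frac <- tapply(eff$synonymous, key, mean)
  S <- sum(syn_frac)
  total_positions <- length(syn_frac)
  list(N_sites = total_positions - S, S_sites = unname(S),
       n_codons = total_positions %/% 3L)
}

#' Label heteroplasmy calls as synonymous / non-synonymous / non-coding
#'
#' Uses the genome's substitution-effect table (minor allele substituted
#' into the reference codon, ANY-overlapping-frame rule). Also builds
#' the 2x2 shared x (non-synonymous / synonymous) sharing table over the
#' coding calls for [sharing_fisher()], when a `shared` column is
#' present.
#'
#' @param calls data.frame with `pos`, `minor` and optionally `shared`.
#' @param genome a [mito_genome()].
#' @return list: `calls` (input plus `label`), `table` (2x2 matrix or
#'   NULL).
#' @export
classify_heteroplasmies <- function(calls, genome = mito_genome()) {
  eff <- effect_matrix(genome)
  code <- eff[cbind(calls$pos, match(toupper(calls$minor), BASES))]
  calls$label <- c("non-coding", "synonymous", "non-synonymous")[code + 1L]
  tab <- NULL
  if ("shared" %in% names(calls)) {
    coding <- calls[calls$label != "non-coding", , drop = FALSE]
    tab <- matrix(c(
      sum(coding$shared & coding$label == "non-synonymous"),
      sum(!coding$shared & coding$label == "non-synonymous"),
      sum(coding$shared & coding$label == "synonymous"),
      sum(!coding$shared & coding$label == "synonymous")), 2L, 2L,
      dimnames = list(c("shared", "not_shared"),
                      c("non-synonymous", "synonymous")))
  }
  list(calls = calls, table = tab)
}

# Per-(position, alt) integer matrices counting in how many gene frames
# the substitution is synonymous / non-synonymous. Consistent with the
# per-gene site denominators: overlapping frames contribute separately,
# so the full substitution space has hN/hS = 1 exactly.
effect_count_matrices <- function(genome) {
  if (!is.null(genome$cache$effcnt)) return(genome$cache$effcnt)
  eff <- substitution_effects(genome)
  L <- genome$length
  syn <- nonsyn <- matrix(0L, L, 4L, dimnames = list(NULL, BASES))
  if (nrow(eff)) {
    key <- (eff$pos - 1L) * 4L + match(eff$alt, BASES)
    syn[] <- matrix(tabulate(key[eff$synonymous], nbins = 4L * L),
                    ncol = 4L, byrow = TRUE)
    nonsyn[] <- matrix(tabulate(key[!eff$synonymous], nbins = 4L * L),
                       ncol = 4L, byrow = TRUE)
  }
  genome$cache$effcnt <- list(syn = syn, nonsyn = nonsyn)
  genome$cache$effcnt
}

#' hN/hS selection statistic
#'
#' hN = non-synonymous heteroplasmies per non-synonymous site, hS =
#' synonymous heteroplasmies per synonymous site; each heteroplasmy
#' occurrence counts once per gene frame it falls in (substitutions in
#' the short ATP8/ATP6 and ND4L/ND4 overlaps count in both frames,
#' matching the site denominators, so the full substitution space yields
#' exactly 1). The ratio is 1 under neutrality, > 1 under positive
#' selection for amino-acid changes. With zero synonymous heteroplasmies
#' the ratio is undefined (NA, reported).
#'
#' @param calls data.frame with `pos`, `minor` (coding and non-coding
#'   rows; non-coding rows are ignored).
#' @param genome a [mito_genome()].
#' @return list of class `hnhs_result`: `n_nonsyn_het`, `n_syn_het`,
#'   `N_sites`, `S_sites`, `hN`, `hS`, `ratio`.
#' @export
hn_hs <- function(calls, genome = mito_genome()) {
  cm <- effect_count_matrices(genome)
  sites <- count_syn_nonsyn_sites(genome)
  idx <- cbind(as.integer(calls$pos), match(toupper(calls$minor), BASES))
  n_n <- sum(cm$nonsyn[idx])
  n_s <- sum(cm$syn[idx])
  hN <- n_n / sites$N_sites
  hS <- n_s / sites$S_sites
  structure(list(n_nonsyn_het = n_n, n_syn_het = n_s,
                 N_sites = sites$N_sites, S_sites = sites$S_sites,
                 hN = hN, hS = hS,
                 ratio = if (n_s > 0) hN / hS else NA_real_),
            class = "hnhs_result")
}

#' @export
print.hnhs_result <- function(x, ...) {
  cat(sprintf("hN/hS = %s (hN = %d/%.1f, hS = %d/%.1f)\n",
              format(x$ratio, digits = 4), x$n_nonsyn_het, x$N_sites,
              x$n_syn_het, x$S_sites))
  invisible(x)
}

#' Permutation null for hN/hS
#'
#' Each permutation re-places the same substitutions as observed --
#' preserving each substitution's reference-strand base change (a G>A
#' stays a G>A) -- at uniformly random coding positions where the
#' reference base matches, and recomputes hN/hS. p = (b+1)/(n_perm+1)
#' with b the number of permuted ratios >= the observed ratio.
#'
#' @param calls observed coding heteroplasmies (`pos`, `minor`).
#' @param genome a [mito_genome()].
#' @param n_perm permutations (1000).
#' @param seed RNG seed.
#' @return list: `ratio_obs`, `null_ratios`, `p_perm`, `n_perm`, `seed`.
#' @export
hn_hs_permutation_null <- function(calls, genome = mito_genome(),
                                   n_perm = 1000L, seed = 1L) {
  if (n_perm < 1L) stop("n_perm must be >= 1")
  obs <- hn_hs(calls, genome)
  cm <- effect_count_matrices(genome)
  coding_pos <- which(rowSums(cm$syn + cm$nonsyn) > 0)
  pos_by_base <- split(coding_pos, genome$seq[coding_pos])
  idx <- cbind(as.integer(calls$pos), match(toupper(calls$minor), BASES))
  is_coding <- (cm$syn + cm$nonsyn)[idx] > 0
  coding <- calls[is_coding, , drop = FALSE]
  refb <- genome$seq[coding$pos]
  altb <- toupper(coding$minor)
  if (any(!refb %in% names(pos_by_base)))
    stop("no coding positions carry a required reference base")
  sites <- count_syn_nonsyn_sites(genome)
  alt_idx <- match(altb, BASES)
  base_pool <- pos_by_base[refb]
  set.seed(seed)
  null_ratios <- vapply(seq_len(n_perm), function(i) {
    newpos <- vapply(base_pool, function(p)
      if (length(p) == 1L) p else sample(p, 1L), integer(1))
    ii <- cbind(newpos, alt_idx)
    n_n <- sum(cm$nonsyn[ii]); n_s <- sum(cm$syn[ii])
    if (n_s == 0L) Inf else (n_n / sites$N_sites) / (n_s / sites$S_sites)
  }, numeric(1))
  b <- sum(null_ratios >= obs$ratio)
  list(ratio_obs = obs$ratio, null_ratios = null_ratios,
       p_perm = perm_pvalue(b, n_perm), n_perm = n_perm, seed = seed)
}

#' Heteroplasmy counts by age group with Mann-Whitney tests
#'
#' Splits individuals at the age cut (default 60 years), counts
#' synonymous and non-synonymous heteroplasmies per individual, tests
#' each label with a two-sided Mann-Whitney U test and adjusts the two
#' p-values with Benjamini-Hochberg.
#'
#' @param calls data.frame with `individual`, `pos`, `minor`.
#' @param ages data.frame `individual`, `age` (every cohort individual,
#'   including those with zero coding calls).
#' @param genome a [mito_genome()].
#' @param cut age cut in years (60); groups are `age < cut` vs
#'   `age >= cut`.
#' @return list: `counts` (per individual x label), `tests` data.frame
#'   (label, p, p_adj).
#' @export
age_group_counts <- function(calls, ages, genome = mito_genome(), cut = 60) {
  stopifnot(all(calls$individual %in% ages$individual))
  lab <- classify_heteroplasmies(calls, genome)$calls$label
  grp <- ifelse(ages$age < cut, "young", "old")
  if (length(unique(grp)) < 2L) stop("an age group is empty")
  counts <- data.frame(individual = ages$individual, age = ages$age,
                       group = grp, stringsAsFactors = FALSE)
  res <- lapply(c("synonymous", "non-synonymous"), function(l) {
    per_ind <- vapply(ages$individual, function(id)
      sum(calls$individual == id & lab == l), integer(1))
    counts[[l]] <<- per_ind
    stats::wilcox.test(per_ind[grp == "young"], per_ind[grp == "old"],
                       exact = FALSE)$p.value
  })
  p <- unlist(res)
  list(counts = counts,
       tests = data.frame(label = c("synonymous", "non-synonymous"),
                          p = p, p_adj = bh_adjust(p),
                          stringsAsFactors = FALSE))
}
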