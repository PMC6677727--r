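---
title: "Models and methods behind hetshare"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hetshare}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(hetshare)
```

# The problem

A human cell carries hundreds to thousands of mitochondrial genomes.
When two alleles coexist at one position within an individual the site
is *heteroplasmic*, and the minor allele frequency (MAF) measures the
mixture. Somatic heteroplasmies accumulate with age in a
tissue-specific way. `hetshare` asks a population-genetic question of
such data: when the same tissue is sampled twice (here, the two primary
lobes of the liver, plus blood as a reference tissue), how often is a
heteroplasmy present in both samples, how similar are its MAFs, and are
the observed patterns compatible with neutral processes — random
genetic drift from a common progenitor cell, recurrent mutation — or do
they require selection?

The package implements the full analysis path on strand-resolved
allele-count tables: calling, QC and contamination screening, sharing
and correlation statistics with resampling nulls, a drift simulator
with a variance test, hN/hS selection statistics, and a synthetic
cohort generator that makes every stage testable without sequencing
data.

# Coordinate system and gene model

Positions are 1-based on the 16,569-bp rCRS circle. The control region
is 16,024–576 (wrapping the origin), the non-control region 577–16,023,
the D-loop 16,097–191 (outer limits of 7S DNA binding), and four
repeat-prone intervals (302–316, 513–526, 566–573, 16,181–16,194) are
excluded from calling. The 13 protein-coding genes ship with their real
rCRS coordinates; ND6 is read on the light strand. Genes ending in
incomplete stop codons (completed in vivo by polyadenylation) are
trimmed to complete codons; the trailing bases are non-codon positions
and never enter synonymous/non-synonymous bookkeeping.

The packaged reference *sequence* is synthetic: a seeded random
16,569-nt string (`synthetic_reference()`), because the true rCRS bases
are not redistributed with the package. Region arithmetic, codon frames
and all acceptance-relevant statistics are coordinate-level and do not
depend on the base content; any user can supply the real rCRS FASTA via
`mito_genome("rCRS.fasta")`.

Substitutions are classified by substituting the minor allele into the
affected codon and translating with the vertebrate mitochondrial code
(table 2; AGA/AGG stop, ATA Met, TGA Trp). For the two overlapping gene
pairs (ATP8/ATP6, ND4L/ND4) a substitution is *labelled*
non-synonymous if it is non-synonymous in any frame — a conservative
choice, since the original analysis does not state how overlapping
frames were fed to its Ka/Ks machinery.

# The calling filter cascade

A site in a sample is a heteroplasmy iff all of the following hold
(`filter_config()` defaults; every "at least" is inclusive):

* MAF ≥ 2.5% on the forward and on the reverse strand;
* total depth ≥ 500×;
* ≥ 10 reads supporting the minor allele on each strand;
* a per-strand quality score ≥ 10, *waived* at the tissue's common
  heteroplasmic sites (liver: 60, 72, 94, 185, 189, 203, 11,126,
  16,093, 16,126; blood: 12,705) — the waiver touches only the quality
  criterion, all others still apply;
* the position is not in an excluded repeat region;
* the site's depth is within 20–200% of the sample mean depth (the
  *mean* is used; whether the original pipeline used mean or median is
  unstated).

MAF is always oriented to the **blood** major allele of the same
individual, so a liver consensus that differs from blood legitimately
yields MAF > 0.5 (flagged `consensus_flip`). Ties between candidate
minor alleles break toward the higher combined-strand count, then
alphabetically, and are flagged. The decision is a pure conjunction:
rejection reasons are recorded per criterion and are order-independent.

The upstream pipeline that motivated this design has an internal
"heteroplasmic quality score" that is not re-derivable from its
description. The substitute here is a binomial error tail:
score = −10·log₁₀ P(X ≥ k) with X ~ Binomial(strand depth, error rate
0.001). It is exact, monotone in the minor count, and an externally
supplied `quality_fwd`/`quality_rev` column takes precedence, so data
scored by the original pipeline pass through unchanged.

Sample-level QC drops an individual when any of their samples has
strictly more than 2% of the genome below 500× . Two contamination
screens run across individuals (liver-vs-liver and blood-vs-blood):
the pairwise screen flags a recipient when (1) at ≥ 80% of
differing-consensus sites its minor allele equals the donor major, (2)
the mean MAF at those sites is ≥ 1%, and (3) ≥ 60% of its
minor-bearing sites were called heteroplasmic; with zero
differing-consensus sites the pair is clear — a contaminant requires
observable donor signal. The haplogroup-excess rule drops an
individual when ≥ 5 of its minor alleles jointly match another
sample's consensus where that consensus differs from its own.

# Sharing and correlation statistics

MAF pairs between two tissues include every (individual, position)
called in *at least one* tissue; the other tissue contributes its raw,
identically oriented MAF even below threshold. Sharing means called in
both. The 2×2 table (shared/not × control/non-control, or ×
non-synonymous/synonymous) is tested with a two-sided Fisher exact
test, computed directly as the sum of hypergeometric probabilities ≤
the observed table's probability.

Significance of Pearson correlations is assessed by permutation:
shuffle one vector, count permutations with |r| ≥ |r observed|, report
(b+1)/(n+1) — the add-one estimator is never zero and is valid at any
permutation count. Two further resampling tests mirror the study
design:

* the **random-partition test** re-partitions all pairs into sets of
  the observed control/non-control sizes and asks whether the observed
  difference in r is extreme (one-sided, in the claimed direction; a
  two-sided flag exists);
* the **subsampling test** draws same-size random subsets of the
  control-region pairs and asks whether the recurrent sites (60/72/94)
  have an unusually high r.

Permutations are pooled across the site list (not stratified by
individual), matching the original description of "randomly permuting
the data"; the known flaw that individuals contribute multiple
non-independent sites is reproduced deliberately. |ΔMAF|-vs-age
correlations use the same permutation machinery, optionally per site
for positions with ≥ 20 heteroplasmic individuals. Families of
correlation p-values are Benjamini–Hochberg adjusted (own step-up
implementation, tested against `p.adjust`).

# The drift simulator

The two-step model: a cell with N mtDNA molecules (k minor) divides;
molecules segregate equally and without replacement, so daughter 1
receives k₁ ~ Hypergeometric(N, k, N/2); each daughter then replicates
every molecule once, returning to N with 2k₁ minor copies. All drift
comes from segregation. Deterministic doubling is the minimal reading
of "re-gain the same number of copies"; a Pólya-type stochastic
replication is available behind `replication = "polya"` for sensitivity
analysis.

A pedigree starts at round(p₀·N) minor molecules; the first division
creates the two sides (anti-correlated by the shared split), and each
side then follows one random daughter per generation — equivalent in
distribution to sampling one random leaf per side, since every lineage
is exchangeable under this kernel. At generations 10/20/50/100/250 the
absolute MAF difference between the sides is recorded; the default
grid is N ∈ {1,000, 2,500, 5,000} × p₀ ∈ {5, 10, 20, 50%} × 1,000
replicates. The grid cell closest to the observed mean copy number
(log-scale) and mean shared-heteroplasmy MAF is selected
lexicographically, and a one-sided F-test (F = var(simulated) /
var(observed)) asks whether the observed between-lobe MAF differences
are *less* variable than drift predicts.

The simulator is validated against exact propagation of the
(N+1)-state Markov chain for small N, plus martingale (mean minor
fraction constant at p₀), absorption and fixation-probability
invariants.

# hN/hS

Site counting is unweighted NG86: each codon position contributes a
synonymous fraction (number of the 3 substitutions preserving the
amino acid)/3; S is their sum, N = 3·codons − S. At heteroplasmy
densities (≪ 1 change per codon) the multiple-hit corrections of
evolutionary Ka/Ks estimators are void, so this counting definition
matches the verbal definition of hN/hS; numeric agreement with any
particular Ka/Ks implementation is not claimed. Stop-gain (and
stop-loss) substitutions count as non-synonymous.

One design point deserves a note: labels use the ANY-frame rule, but
the site denominators count overlapping frames separately. Counting
numerator occurrences per overlapping gene frame as well makes the
identity exact — the hN/hS of the complete substitution space is 1 by
construction, which the tests assert to machine precision. The
reporting label of a call remains the single ANY-frame label.

The permutation null re-places the observed substitutions — each
keeping its heavy-strand base change, e.g. a G→A stays a G→A — at
uniformly random coding positions with a matching reference base, and
recomputes the ratio; p = (b+1)/(n+1) for permuted ratios ≥ observed.
Age-group comparisons split at 60 years and test per-individual
synonymous and non-synonymous counts with two-sided Mann–Whitney U
tests, BH-adjusted.

# The synthetic cohort

The generator emits what the caller consumes: per-sample strand-
resolved count tables. Its defaults are the stated world of the
analysis — 83 individuals aged 24–94 (uniform), three samples each,
mean depths 1,175× (blood) / 2,640× (liver), recurrent liver sites with
occurrence probabilities from the printed individual counts (72:
67/83, 60: 26/83, 94: 20/83, the rarer common sites 6/83), sharing
probabilities 55% (control) / 7.5% (non-control) for a liver
heteroplasmy to appear in both lobes, and a Beta(2, 16.5) true-MAF
distribution (mean 10.8%).

Where no generative model is stated, the package chooses once:

* heteroplasmy counts per individual are Poisson with rate linear in
  age (control 0.5 + 0.034·age, non-control 0.3 + 0.052·age), fixed so
  that the cohort means reproduce the observed totals (~2.5 and ~3.4
  sites per individual) at the mean age of 59 — the observed
  count–age correlation is r ≈ 0.4, but only a linear-rate Poisson is
  assumed;
* blood rates are 0.15× the liver rates;
* the second lobe's MAF at shared sites is the first plus Gaussian
  jitter (sd 0.02, truncated to [0,1] by inverse-CDF sampling);
* reads are Binomial(depth, MAF) with a symmetric Binomial(0.5) strand
  split (no strand bias is modelled), Poisson depth per site, and a
  0.1% error rate spread uniformly over the three non-consensus
  alleles;
* each individual carries ~Poisson(25) private homoplasmic haplotype
  variants, which is what gives the contamination screens signal;
  `inject_contamination()` mixes donor allele fractions into a
  recipient at a chosen fraction and re-samples counts binomially.

What the generator does **not** emulate: read-level artefacts
(alignment error, index hopping, strand bias, GC-coverage waves),
linked heteroplasmies on a molecule, real haplogroup phylogeny, 7S DNA
and indels. A green parameter-recovery test therefore establishes that
the statistical pipeline is correct under the stated sampling model,
not that the caller is robust to artefacts the model omits.

# Numerical choices and degenerate inputs

* All resampling uses the add-one p estimator; every stochastic
  operation takes an explicit seed and is bit-reproducible.
* Permutation tests directional per the claim tested; two-sided
  variants via flags.
* Zero-depth sites, constant vectors (undefined r), zero-variance
  F-tests, empty partitions, zero-margin tables and alt == ref
  substitutions all raise errors rather than silently returning.
* Quality scores are computed on log scale (`pbinom(log.p = TRUE)`) to
  avoid underflow, capped at 999.
* The coverage-band and sample-QC comparisons are strict/inclusive
  exactly as worded ("more than 2%" strict; every "at least"
  inclusive).

# Known limitations

* The pairwise contamination screen is quadratic in cohort size; the
  pipeline exposes `screens = FALSE` for simulation studies without
  contamination.
* hN/hS is aggregate (no per-gene ratios) and unweighted by MAF.
* The copy-number estimate is mean depth × 1/150 — a calibration
  carried over from capture-enrichment practice; only its relative
  scale matters here.
* Indel heteroplasmies and VCF emission are out of scope.
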