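# hetshare

Mitochondrial DNA (mtDNA) is present in hundreds to thousands of copies
per cell; a position where two alleles coexist within an individual is
*heteroplasmic*, quantified by the minor allele frequency (MAF).
Somatic heteroplasmies accumulate with age and are strikingly
tissue-specific. `hetshare` is an R toolkit for a population-genetic
question about such data: when the same tissue is sampled twice — e.g.
one sample from each primary lobe of the liver, with blood as a
reference tissue — how often is a heteroplasmy **shared** between the
samples, how similar are its MAFs, and can neutral explanations
(random genetic drift from a common progenitor cell, recurrent
mutation, blood admixture) account for the sharing, or is selection
required?

The package is aimed at researchers analysing deep mtDNA sequencing of
multi-sample autopsy or biopsy cohorts, and at anyone who wants a
fully simulatable, testable re-implementation of this analysis style.

## What it computes

* **Calling** — heteroplasmies from strand-resolved allele-count
  tables via the standard filter cascade: per-strand MAF ≥ 2.5%,
  depth ≥ 500×, ≥ 10 minor reads per strand, per-strand quality ≥ 10
  (a binomial-error-tail score, waived at known common sites such as
  60/72/94 in liver), repeat-region exclusion, a 20–200% coverage
  band; plus sample QC and two cross-sample contamination screens.
  MAF is oriented to the blood major allele.
* **Sharing statistics** — shared × region 2×2 tables with two-sided
  Fisher exact tests; Pearson correlations of MAFs between samples
  with permutation p-values `(b+1)/(n+1)`; a random-partition test for
  a difference in correlation between genome regions; a subsampling
  test for site-driven correlation; |ΔMAF|-vs-age correlations;
  Benjamini–Hochberg adjustment.
* **Drift simulation** — the two-step model: each cell division
  segregates the N mtDNA molecules hypergeometrically into two
  daughters, which double back to N. |ΔMAF| between the two sides of a
  pedigree is recorded over a (N, p₀) grid, and a one-sided F-test
  asks whether observed between-lobe MAF differences are *less*
  variable than drift predicts: F = Var(sim)/Var(obs).
* **Selection** — hN/hS: non-synonymous heteroplasmies per
  non-synonymous site over synonymous heteroplasmies per synonymous
  site (unweighted NG86 site counts under the vertebrate mitochondrial
  code; expectation 1 under neutrality), with a permutation null that
  re-places the observed base changes uniformly over the coding region.
* **Worked calculators** — blood-admixture calling threshold
  (2.5% × 9 = 22.5%), liver doublings (⌈log₂ 3.61×10¹¹⌉ = 39), mtDNA
  turnover under relaxed replication, coverage-derived relative copy
  number, D-loop vs rest coverage comparison.
* **Synthetic cohorts** — a seeded generator producing count tables
  with the full statistical structure (age-dependent heteroplasmy
  counts, recurrent sites, tunable lobe sharing, private haplotype
  variants, strand-split binomial reads, sequencing error, optional
  injected contamination), so the whole pipeline runs and is tested
  without any sequencing data.

## Worked example

```r
library(hetshare)

res <- run_pipeline(run_config(
  cohort = cohort_config(n_individuals = 40),   # synthetic autopsy cohort
  drift  = drift_config(replicates = 300),
  n_perm = 300, seed = 11, screens = FALSE))

res$share$table
#>            control noncontrol
#> shared          82         18
#> not_shared      75        134
round(res$share$shared_fraction, 1)
#>    control noncontrol    overall
#>       52.2       11.8       32.4
res$share$fisher_p
#> [1] 1.06e-14
res$share$partition$p_perm        # control vs non-control difference in r
#> [1] 0.00332
res$drift$cell[c("N", "p0")]      # grid cell matched to the cohort
#> $N   [1] 2500
#> $p0  [1] 0.1
res$drift$f_test$p                # observed lobes less variable than drift
#> [1] 1.76e-32
res$selection$hnhs
#> hN/hS = 0.8657 (hN = 87/8837.7, hS = 29/2550.3)
```

Reading the output: of 309 liver heteroplasmies in this simulated
cohort, 52% of control-region sites but only 12% of non-control sites
were called in both lobes (Fisher p ≈ 10⁻¹⁴), the control region's MAF
correlation exceeds the non-control one by more than random partitions
allow (p = 0.003, the add-one floor at 300 permutations), and the
between-lobe MAF differences are far less variable than 50 generations
of drift at the matched copy number would produce (p ≈ 10⁻³²) — the
qualitative signature the package is built to detect. The generator
placed substitutions without selection, so hN/hS is near 1.

A command-line wrapper is included:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/hetshare.R", package="hetshare"))')" \
    run --seed 1 --out out/
```

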