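Package: hetshare
Title: Mitochondrial Heteroplasmy Calling and Tissue-Sharing Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to study the sharing of mitochondrial DNA (mtDNA)
    heteroplasmies between tissue samples, in particular between the two
    lobes of the human liver. Provides a heteroplasmy caller for
    strand-resolved allele-count tables with the canonical filter cascade
    (minor allele frequency, depth, per-strand support, binomial quality
    score, coverage band, repeat-region exclusion), sample-level QC and
    cross-sample contamination screens; sharing and correlation statistics
    with permutation, random-partition and subsampling nulls; a two-step
    random genetic drift simulator for mtDNA segregation with a variance
    test against observed minor allele frequency differences; an hN/hS
    selection statistic over the mitochondrial protein-coding genes with a
    permutation null; coverage-derived copy-number utilities; and a
    synthetic autopsy-cohort generator so that the whole pipeline is
    testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    Biostrings,
    optparse
Config/testthat/edition: 3
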