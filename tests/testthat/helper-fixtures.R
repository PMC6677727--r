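# Shared fixtures and independent oracles, built in code.

BASES4 <- c("A", "C", "G", "T")

# small circular genome: one heavy-strand gene (10 codons, pos 10-39)
# and one light-strand gene (8 codons, pos 61-84), plus an extra base at
# the gene end to exercise incomplete-codon trimming (gene2 spans 60-84,
# 25 bp -> 8 complete codons read from 84 downwards).
toy_genome <- function(seed = 42) {
  set.seed(seed)
  seq <- sample(BASES4, 120, replace = TRUE)
  ann <- data.frame(
    gene = c("g_plus", "g_minus"),
    start = c(10L, 60L),
    end = c(39L, 84L),
    strand = c("+", "-"),
    stringsAsFactors = FALSE
  )
  mito_genome(seq, ann, map = NULL)
}

comp <- c(A = "T", C = "G", G = "C", T = "A")

# brute-force syn/non-syn oracle: rebuild the complete-codon CDS of each
# gene, substitute, translate whole proteins with Biostrings table 2,
# compare. Aggregates over overlapping genes with the ANY-frame rule.
oracle_classify <- function(pos, alt, genome) {
  gc2 <- Biostrings::getGeneticCode("2")
  translate_cds <- function(cds) {
    n <- length(cds) %/% 3L
    codons <- paste0(cds[3 * seq_len(n) - 2], cds[3 * seq_len(n) - 1],
                     cds[3 * seq_len(n)])
    paste(gc2[codons], collapse = "")
  }
  labels <- character(0)
  for (i in seq_len(nrow(genome$annotation))) {
    a <- genome$annotation[i, ]
    ncod <- (a$end - a$start + 1L) %/% 3L
    if (a$strand == "+") {
      cds_pos <- seq.int(a$start, a$start + 3L * ncod - 1L)
      cds <- genome$seq[cds_pos]
      sub_allele <- alt
    } else {
      cds_pos <- seq.int(a$end, a$end - 3L * ncod + 1L)
      cds <- unname(comp[genome$seq[cds_pos]])
      sub_allele <- unname(comp[alt])
    }
    j <- match(pos, cds_pos)
    if (is.na(j)) next
    prot_ref <- translate_cds(cds)
    cds[j] <- sub_allele
    labels <- c(labels,
                if (translate_cds(cds) == prot_ref) "synonymous"
                else "non-synonymous")
  }
  if (!length(labels)) return("non-coding")
  if (any(labels == "non-synonymous")) "non-synonymous" else "synonymous"
}

# strand-resolved count row(s) from per-allele totals, split evenly by
# default or by explicit fwd counts
make_counts <- function(pos, A = 0, C = 0, G = 0, T = 0,
                        A_fwd = NULL, C_fwd = NULL, G_fwd = NULL,
                        T_fwd = NULL, ref = "A") {
  half <- function(tot, fwd) if (is.null(fwd)) ceiling(tot / 2) else fwd
  af <- half(A, A_fwd); cf <- half(C, C_fwd)
  gf <- half(G, G_fwd); tf <- half(T, T_fwd)
  data.frame(pos = pos, ref = ref,
             A_fwd = af, C_fwd = cf, G_fwd = gf, T_fwd = tf,
             A_rev = A - af, C_rev = C - cf, G_rev = G - gf, T_rev = T - tf)
}

# uniform draw of coding substitutions (positions uniform over coding
# positions, alt uniform over the 3 non-reference bases)
uniform_coding_calls <- function(genome, m) {
  eff <- hetshare:::effect_matrix(genome)
  cp <- which(rowSums(eff > 0) > 0)
  pos <- sample(cp, m, replace = TRUE)
  alt <- vapply(pos, function(p)
    sample(setdiff(BASES4, genome$seq[p]), 1L), character(1))
  data.frame(pos = pos, minor = alt, stringsAsFactors = FALSE)
}

COUNT_COLS0 <- c(paste0(BASES4, "_fwd"), paste0(BASES4, "_rev"))
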