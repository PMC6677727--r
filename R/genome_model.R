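# Circular mtDNA coordinate system, region partition and codon-level
# substitution classification under the vertebrate mitochondrial code.

#' Length of the human mtDNA reference (rCRS numbering)
#' @export
MT_GENOME_LENGTH <- 16569L

# Vertebrate mitochondrial genetic code (translation table 2).
# Differs from the standard code at AGA/AGG (Stop), ATA (Met), TGA (Trp).
MT_GENETIC_CODE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "M", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "W", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "*", AGG = "*",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

#' Region partition of the mtDNA genome
#'
#' Returns the standard partition of the rCRS coordinate system into the
#' control region (16,024-576, wrapping the origin) and the non-control
#' region (577-16,023), together with the D-loop interval (16,097-191,
#' the outer limits of 7S DNA binding) and the repeat-prone regions that
#' are excluded from heteroplasmy calling (302-316, 513-526, 566-573,
#' 16,181-16,194).
#'
#' @return A list of class `region_map` with integer position vectors
#'   `control`, `noncontrol`, `dloop`, `excluded`.
#' @export
region_map <- function() {
  ctrl <- c(16024:16569, 1:576)
  structure(list(
    control    = ctrl,
    noncontrol = 577:16023,
    dloop      = c(16097:16569, 1:191),
    excluded   = c(302:316, 513:526, 566:573, 16181:16194)
  ), class = "region_map")
}

#' Classify genome positions into control / non-control region
#'
#' Vectorised over `pos`. Each position belongs to exactly one of the
#' control region (16,024-576, wrapping the origin) or the non-control
#' region (577-16,023); D-loop membership and excluded-region membership
#' are reported as independent flags.
#'
#' @param pos integer vector of 1-based rCRS positions.
#' @param map a `region_map`, by default [region_map()].
#' @return data.frame with columns `pos`, `region` ("control" or
#'   "noncontrol"), `dloop`, `excluded` (logical).
#' @examples
#' classify_region(c(72, 10000, 310, 16100))
#' @export
classify_region <- function(pos, map = region_map()) {
  pos <- as.integer(pos)
  if (any(is.na(pos)) || any(pos < 1L) || any(pos > MT_GENOME_LENGTH))
    stop("positions must be in 1..", MT_GENOME_LENGTH)
  data.frame(
    pos = pos,
    region = ifelse(pos %in% map$control, "control", "noncontrol"),
    dloop = pos %in% map$dloop,
    excluded = pos %in% map$excluded,
    stringsAsFactors = FALSE
  )
}

#' Wrap a position onto the circular genome
#'
#' @param pos integer vector (may be outside 1..L).
#' @param length genome length.
#' @return positions wrapped modulo the genome length into 1..L.
#' @export
wrap_position <- function(pos, length = MT_GENOME_LENGTH) {
  ((as.integer(pos) - 1L) %% length) + 1L
}

#' The packaged mtDNA protein-coding gene annotation
#'
#' Coordinates (1-based, inclusive, rCRS numbering) of the 13
#' protein-coding genes of the human mitochondrial genome. ND6 is encoded
#' on the light strand and is translated from the reverse complement.
#' Several genes end in incomplete stop codons completed by
#' polyadenylation; the trailing 1-2 bases are not part of any complete
#' codon and are treated as non-codon positions.
#'
#' @return data.frame with columns `gene`, `start`, `end`, `strand`.
#' @export
mt_gene_table <- function() {
  path <- system.file("extdata", "rcrs_genes.tsv", package = "hetshare")
  read_annotation(path)
}

#' Read a gene annotation table
#'
#' BED-like, but 1-based inclusive (see the packaged default); columns
#' `gene`, `start`, `end`, `strand` ("+" heavy / "-" light). Tools that
#' emit genuine BED (0-based half-open) must shift `start` by +1 first.
#'
#' @param path TSV file path.
#' @return data.frame annotation.
#' @export
read_annotation <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "start", "end", "strand")
  if (!all(need %in% names(ann)))
    stop("annotation must have columns: ", paste(need, collapse = ", "))
  stopifnot(all(ann$strand %in% c("+", "-")), all(ann$end >= ann$start))
  ann
}

#' Synthetic circular mtDNA reference sequence
#'
#' A seeded random 16,569 nt sequence used as a stand-in for the rCRS
#' when no reference FASTA is supplied (the true rCRS sequence is not
#' shipped). The gene coordinate system is the real rCRS one, so region
#' arithmetic and codon bookkeeping are faithful; only the base content
#' is synthetic. Any analysis that depends on the actual rCRS bases must
#' supply its own FASTA via [mito_genome()].
#'
#' @param length genome length.
#' @param seed RNG seed for the base draw (fixed default so that the
#'   packaged genome is identical everywhere).
#' @return character vector of single bases.
#' @export
synthetic_reference <- function(length = MT_GENOME_LENGTH, seed = 16569L) {
  with_preserved_rng(seed, {
    sample(BASES, length, replace = TRUE, prob = c(0.31, 0.31, 0.13, 0.25))
  })
}

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards. Keeps package-internal seeding from
# interfering with user simulations.
with_preserved_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Read a single-contig FASTA into a base vector
#'
#' Uses Biostrings when available, otherwise a minimal reader.
#'
#' @param path FASTA path (one circular contig).
#' @return upper-case character vector of single bases.
#' @export
read_reference <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    ss <- Biostrings::readDNAStringSet(path)
    if (length(ss) != 1L) stop("expected a single contig in ", path)
    return(strsplit(toupper(as.character(ss[[1]])), "")[[1]])
  }
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, ">")]
  strsplit(toupper(paste(lines, collapse = "")), "")[[1]]
}

#' Assemble a mitochondrial genome object
#'
#' Bundles the reference sequence, the protein-coding gene annotation and
#' the region partition, and lazily caches the per-position substitution
#' effect table used by the selection statistics.
#'
#' @param reference character vector of bases, or a FASTA path, or NULL
#'   for the packaged synthetic reference.
#' @param annotation annotation data.frame (see [read_annotation()]), a
#'   TSV path, or NULL for the packaged rCRS gene table.
#' @param map a `region_map` (defaults to the rCRS partition when the
#'   genome has the rCRS length, otherwise NULL).
#' @return object of class `mito_genome` with fields `seq`, `length`,
#'   `annotation`, `map`.
#' @export
mito_genome <- function(reference = NULL, annotation = NULL, map = NULL) {
  if (is.null(reference)) reference <- synthetic_reference()
  if (is.character(reference) && length(reference) == 1L &&
      file.exists(reference)) reference <- read_reference(reference)
  reference <- toupper(reference)
  if (!all(reference %in% BASES))
    stop("reference contains non-ACGT characters")
  if (is.null(annotation)) {
    annotation <- if (length(reference) == MT_GENOME_LENGTH)
      mt_gene_table()
    else
      data.frame(gene = character(), start = integer(), end = integer(),
                 strand = character(), stringsAsFactors = FALSE)
  } else if (is.character(annotation) && length(annotation) == 1L) {
    annotation <- read_annotation(annotation)
  }
  if (nrow(annotation) && max(annotation$end) > length(reference))
    stop("annotation extends beyond the reference")
  if (is.null(map) && length(reference) == MT_GENOME_LENGTH)
    map <- region_map()
  g <- structure(list(
    seq = reference,
    length = length(reference),
    annotation = annotation,
    map = map,
    cache = new.env(parent = emptyenv())
  ), class = "mito_genome")
  g
}

#' @export
print.mito_genome <- function(x, ...) {
  cat("<mito_genome> ", x$length, " bp, ",
      nrow(x$annotation), " protein-coding genes\n", sep = "")
  invisible(x)
}

# Per-gene codon layout restricted to complete codons. Returns for each
# gene a data.frame: genome pos, reading-order index, codon index, codon
# position (1..3) and the reading-strand base.
gene_codon_layout <- function(genome, gene_row) {
  with(gene_row, {
    len <- end - start + 1L
    ncod <- len %/% 3L
    if (ncod == 0L) return(NULL)
    if (strand == "+") {
      pos <- seq.int(start, start + 3L * ncod - 1L)
      base <- genome$seq[pos]
    } else {
      # light strand: reading order runs from `end` downwards on the
      # complement; incomplete bases (if any) are at the low-coordinate end
      pos <- seq.int(end, end - 3L * ncod + 1L)
      base <- unname(COMPLEMENT[genome$seq[pos]])
    }
    data.frame(
      pos = pos,
      codon = rep(seq_len(ncod), each = 3L),
      cpos = rep(1:3, ncod),
      base = base,
      stringsAsFactors = FALSE
    )
  })
}

# Enumerate every possible single-base substitution in the complete
# codons of one gene and classify it as synonymous / non-synonymous.
# Alleles are reported on the heavy (reference) strand.
gene_substitution_effects <- function(genome, gene_row) {
  lay <- gene_codon_layout(genome, gene_row)
  if (is.null(lay)) return(NULL)
  ncod <- max(lay$codon)
  cod <- matrix(lay$base, nrow = 3L)            # 3 x ncod, reading order
  codon_str <- paste0(cod[1, ], cod[2, ], cod[3, ])
  aa_old <- unname(MT_GENETIC_CODE[codon_str])
  out <- vector("list", 9L)
  k <- 0L
  for (cp in 1:3) for (alt in BASES) {
    keep <- cod[cp, ] != alt
    if (!any(keep)) next
    newc <- cod
    newc[cp, ] <- alt
    aa_new <- unname(MT_GENETIC_CODE[paste0(newc[1, ], newc[2, ], newc[3, ])])
    idx <- which(keep)
    rowsel <- (idx - 1L) * 3L + cp
    alt_genome <- if (gene_row$strand == "+") alt else unname(COMPLEMENT[alt])
    k <- k + 1L
    out[[k]] <- data.frame(
      gene = gene_row$gene,
      pos = lay$pos[rowsel],
      alt = alt_genome,
      synonymous = aa_new[idx] == aa_old[idx],
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out[seq_len(k)])
}

# Full substitution effect table: one row per (gene, pos, alt) over all
# complete codons of all genes. Cached on the genome object.
substitution_effects <- function(genome) {
  if (!is.null(genome$cache$effects)) return(genome$cache$effects)
  eff <- do.call(rbind, lapply(seq_len(nrow(genome$annotation)), function(i)
    gene_substitution_effects(genome, genome$annotation[i, ])))
  if (is.null(eff))
    eff <- data.frame(gene = character(), pos = integer(), alt = character(),
                      synonymous = logical(), stringsAsFactors = FALSE)
  genome$cache$effects <- eff
  eff
}

# Aggregated effect lookup: L x 4 integer matrix, 0 = non-coding (or not
# part of a complete codon), 1 = synonymous in every overlapping frame,
# 2 = non-synonymous in at least one frame (conservative ANY-frame rule
# for the overlapping gene pairs ATP8/ATP6 and ND4L/ND4).
effect_matrix <- function(genome) {
  if (!is.null(genome$cache$effmat)) return(genome$cache$effmat)
  eff <- substitution_effects(genome)
  m <- matrix(0L, nrow = genome$length, ncol = 4L,
              dimnames = list(NULL, BASES))
  if (nrow(eff)) {
    code <- ifelse(eff$synonymous, 1L, 2L)
    idx <- cbind(eff$pos, match(eff$alt, BASES))
    # any-frame non-synonymous wins over synonymous
    m[idx] <- pmax(m[idx], code)
  }
  genome$cache$effmat <- m
  m
}

#' Classify single-base substitutions as synonymous / non-synonymous
#'
#' Substitutes the alternate allele into the affected codon(s) and
#' translates with the vertebrate mitochondrial code (table 2). Alleles
#' are given on the heavy (reference) strand; the light-strand gene ND6
#' is classified on the reverse complement internally. Positions outside
#' protein-coding genes, or in the trailing bases of an incomplete stop
#' codon, are `non-coding`. A substitution overlapping two reading frames
#' is non-synonymous if it is non-synonymous in any frame.
#'
#' Vectorised over `pos`, `ref` and `alt`.
#'
#' @param pos genome positions (1-based).
#' @param ref reference alleles at `pos` (checked against the genome).
#' @param alt alternate alleles (must differ from `ref`).
#' @param genome a [mito_genome()].
#' @return character vector: "synonymous", "non-synonymous" or
#'   "non-coding".
#' @export
annotate_substitution <- function(pos, ref, alt, genome = mito_genome()) {
  pos <- as.integer(pos)
  n <- max(length(pos), length(ref), length(alt))
  pos <- rep_len(pos, n); ref <- rep_len(toupper(ref), n)
  alt <- rep_len(toupper(alt), n)
  if (any(pos < 1L | pos > genome$length)) stop("position out of range")
  if (any(!alt %in% BASES) || any(!ref %in% BASES)) stop("alleles must be A/C/G/T")
  if (any(alt == ref)) stop("alt allele equals ref allele")
  bad <- genome$seq[pos] != ref
  if (any(bad))
    stop("ref allele mismatch at position(s) ",
         paste(utils::head(pos[bad], 5L), collapse = ", "))
  m <- effect_matrix(genome)
  code <- m[cbind(pos, match(alt, BASES))]
  c("non-coding", "synonymous", "non-synonymous")[code + 1L]
}
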