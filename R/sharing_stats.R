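# Sharing tables, MAF correlations and the permutation / random-partition
# / subsampling significance procedures.

#' Build MAF pairs between two tissues
#'
#' One pair per (individual, position) at which the site passed the
#' heteroplasmy filters in at least one of the two tissues. The other
#' tissue contributes its raw MAF (same blood-major orientation) even
#' when not called -- these are the "light grey" points of the scatter
#' plots. `shared` marks sites called in both tissues.
#'
#' @param calls_a,calls_b call tables ([call_sample()], one individual's
#'   tissue each, or cohort-long with an `individual` column).
#' @param map a `region_map` for region labels (optional).
#' @return data.frame: `individual`, `pos`, `maf_a`, `maf_b`, `shared`,
#'   `region`.
#' @export
build_maf_pairs <- function(calls_a, calls_b, map = region_map()) {
  for (nm in c("individual")) {
    if (!nm %in% names(calls_a)) calls_a[[nm]] <- "ind"
    if (!nm %in% names(calls_b)) calls_b[[nm]] <- "ind"
  }
  key_a <- paste(calls_a$individual, calls_a$pos)
  key_b <- paste(calls_b$individual, calls_b$pos)
  called_a <- calls_a$pass
  called_b <- calls_b$pass
  keys <- union(key_a[called_a], key_b[called_b])
  if (!length(keys))
    return(data.frame(individual = character(), pos = integer(),
                      maf_a = numeric(), maf_b = numeric(),
                      shared = logical(), region = character(),
                      stringsAsFactors = FALSE))
  ia <- match(keys, key_a)
  ib <- match(keys, key_b)
  skipped <- is.na(ia) | is.na(ib)
  if (any(skipped)) {
    warning(sum(skipped), " site(s) lack raw counts in the partner tissue; skipped")
    keys <- keys[!skipped]; ia <- ia[!skipped]; ib <- ib[!skipped]
  }
  pos <- calls_a$pos[ia]
  out <- data.frame(
    individual = calls_a$individual[ia],
    pos = pos,
    maf_a = calls_a$maf[ia],
    maf_b = calls_b$maf[ib],
    shared = called_a[ia] & called_b[ib],
    stringsAsFactors = FALSE
  )
  out$region <- if (is.null(map)) NA_character_ else
    classify_region(pos, map)$region
  out
}

perm_pvalue <- function(n_extreme, n_perm) (n_extreme + 1) / (n_perm + 1)

#' Pearson correlation with permutation significance
#'
#' Computes Pearson's r between two vectors and a permutation p-value
#' obtained by randomly permuting one vector relative to the other. The
#' two-sided p counts permutations with |r| >= |r observed| and uses the
#' add-one estimator (b+1)/(n_perm+1), so it is never zero.
#'
#' @param x,y numeric vectors (length >= 3), or a MafPair data.frame in
#'   `x` (columns `maf_a`, `maf_b`) with `y` missing.
#' @param n_perm number of permutations (1000).
#' @param seed RNG seed.
#' @param alternative "two.sided" (default), "greater" or "less".
#' @return list of class `correlation_result`: `r`, `n`, `p_perm`,
#'   `n_perm`, `seed`.
#' @export
pearson_r_perm <- function(x, y = NULL, n_perm = 1000L, seed = 1L,
                           alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (is.data.frame(x)) { y <- x$maf_b; x <- x$maf_a }
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant vector: correlation undefined")
  r_obs <- stats::cor(x, y)
  set.seed(seed)
  r_perm <- vapply(seq_len(n_perm), function(i)
    stats::cor(x, sample(y)), numeric(1))
  b <- switch(alternative,
              two.sided = sum(abs(r_perm) >= abs(r_obs)),
              greater = sum(r_perm >= r_obs),
              less = sum(r_perm <= r_obs))
  structure(list(r = r_obs, n = length(x), p_perm = perm_pvalue(b, n_perm),
                 n_perm = n_perm, seed = seed, alternative = alternative),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("r = %.3f (n = %d), permutation p = %.4g (%d permutations)\n",
              x$r, x$n, x$p_perm, x$n_perm))
  invisible(x)
}

#' Two-sided Fisher's exact test on a 2x2 sharing table
#'
#' Exact hypergeometric computation: with margins fixed, the two-sided p
#' is the sum of the probabilities of all tables whose probability does
#' not exceed that of the observed table. A zero margin gives p = 1.
#'
#' @param table 2x2 matrix of non-negative counts (e.g. shared /
#'   not-shared x control / non-control).
#' @return two-sided p-value.
#' @export
sharing_fisher <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == 2L), all(table >= 0))
  r1 <- sum(table[1, ]); r2 <- sum(table[2, ]); c1 <- sum(table[, 1])
  if (r1 == 0 || r2 == 0 || c1 == 0 || sum(table[, 2]) == 0) return(1)
  ks <- max(0, c1 - r2):min(r1, c1)
  pr <- stats::dhyper(ks, r1, r2, c1)
  p_obs <- stats::dhyper(table[1, 1], r1, r2, c1)
  # tolerance guards against ties lost to floating point (as fisher.test)
  min(1, sum(pr[pr <= p_obs * (1 + 1e-7)]))
}

#' Shared fraction of a sharing-table category
#'
#' @param table 2x2 matrix, rows shared / not-shared, columns categories.
#' @param category column index or name.
#' @return percentage 100 * shared / category total.
#' @export
shared_fraction <- function(table, category) {
  table <- as.matrix(table)
  tot <- sum(table[, category])
  if (tot == 0) stop("category total is zero")
  100 * table[1, category] / tot
}

#' Random-partition test for a difference in correlation
#'
#' Tests whether the Pearson correlation in group 1 (e.g. control-region
#' pairs) exceeds that in group 2 by more than expected if group labels
#' were arbitrary: all pairs are randomly re-partitioned into sets of
#' the observed sizes and the difference in r recomputed. One-sided by
#' default (alternative: observed difference larger), matching the
#' directional claim; `two_sided = TRUE` uses |difference|.
#'
#' @param pairs MafPair data.frame (`maf_a`, `maf_b`).
#' @param group1 logical vector marking group-1 pairs (e.g.
#'   `pairs$region == "control"`).
#' @param n_perm permutations (1000).
#' @param seed RNG seed.
#' @param two_sided use |delta r|.
#' @return list: `delta_r`, `r1`, `r2`, `p_perm`, `n_perm`, `seed`.
#' @export
partition_permutation_test <- function(pairs, group1, n_perm = 1000L,
                                       seed = 1L, two_sided = FALSE) {
  stopifnot(length(group1) == nrow(pairs))
  n1 <- sum(group1)
  if (n1 == 0L || n1 == nrow(pairs))
    stop("degenerate partition: a group is empty")
  delta <- function(g1) stats::cor(pairs$maf_a[g1], pairs$maf_b[g1]) -
    stats::cor(pairs$maf_a[!g1], pairs$maf_b[!g1])
  d_obs <- delta(group1)
  set.seed(seed)
  d_perm <- vapply(seq_len(n_perm), function(i) {
    g <- logical(nrow(pairs)); g[sample(nrow(pairs), n1)] <- TRUE
    delta(g)
  }, numeric(1))
  b <- if (two_sided) sum(abs(d_perm) >= abs(d_obs)) else sum(d_perm >= d_obs)
  list(delta_r = d_obs,
       r1 = stats::cor(pairs$maf_a[group1], pairs$maf_b[group1]),
       r2 = stats::cor(pairs$maf_a[!group1], pairs$maf_b[!group1]),
       p_perm = perm_pvalue(b, n_perm), n_perm = n_perm, seed = seed)
}

#' Subsampling test for site-driven correlation
#'
#' Asks whether the correlation at a set of target sites (e.g. the
#' recurrent sites 60/72/94) is higher than for random same-size
#' subsamples of the surrounding population of pairs (e.g. all
#' control-region pairs). The subsample size equals the number of pair
#' occurrences at the target sites.
#'
#' @param pairs population of MafPairs (include the target pairs).
#' @param target logical vector marking target-site pairs.
#' @param n_perm number of random subsamples (1000).
#' @param seed RNG seed.
#' @return list: `r_target`, `n_target`, `null_r` (vector), `p_perm`
#'   (add-one fraction of subsamples with r >= target r).
#' @export
subsample_correlation_test <- function(pairs, target, n_perm = 1000L,
                                       seed = 1L) {
  stopifnot(length(target) == nrow(pairs))
  m <- sum(target)
  if (m == 0L) stop("no target pairs")
  if (m > nrow(pairs)) stop("subsample size exceeds population")
  r_t <- stats::cor(pairs$maf_a[target], pairs$maf_b[target])
  set.seed(seed)
  null_r <- vapply(seq_len(n_perm), function(i) {
    s <- sample(nrow(pairs), m)
    stats::cor(pairs$maf_a[s], pairs$maf_b[s])
  }, numeric(1))
  list(r_target = r_t, n_target = m, null_r = null_r,
       p_perm = perm_pvalue(sum(null_r >= r_t), n_perm),
       n_perm = n_perm, seed = seed)
}

#' Correlation of between-lobe MAF difference with age
#'
#' For shared pairs, |MAF difference| = |maf_a - maf_b| is correlated
#' with the individual's age (Pearson, permutation p). Optionally
#' restricted per site for positions heteroplasmic in at least
#' `min_individuals` individuals (the recurrent-site analysis).
#'
#' @param pairs MafPair data.frame restricted by the caller (typically
#'   `pairs[pairs$shared, ]`).
#' @param ages data.frame `individual`, `age`.
#' @param per_site if TRUE, return one result per qualifying site.
#' @param min_individuals per-site inclusion threshold (20).
#' @param n_perm,seed permutation settings.
#' @return a `correlation_result`, or a list of them (per site).
#' @export
maf_diff_vs_age <- function(pairs, ages, per_site = FALSE,
                            min_individuals = 20L, n_perm = 1000L,
                            seed = 1L) {
  if (nrow(pairs) < 3L) stop("need at least 3 shared pairs")
  age <- ages$age[match(pairs$individual, ages$individual)]
  if (any(is.na(age))) stop("missing age for some individuals")
  d <- abs(pairs$maf_a - pairs$maf_b)
  if (!per_site) return(pearson_r_perm(d, age, n_perm = n_perm, seed = seed))
  tab <- table(pairs$pos)
  keep <- as.integer(names(tab)[tab >= min_individuals])
  res <- lapply(keep, function(p) {
    sel <- pairs$pos == p
    pearson_r_perm(d[sel], age[sel], n_perm = n_perm, seed = seed)
  })
  names(res) <- keep
  res
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate correction with monotonicity
#' enforcement; input order is preserved.
#'
#' @param p numeric p-values in 0..1.
#' @return adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (m <= 1L) return(p)
  o <- order(p, decreasing = TRUE)
  adj <- pmin(1, cummin(p[o] * m / seq(m, 1)))
  adj[order(o)]
}
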