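# Synthetic autopsy-cohort generator: strand-resolved allele counts for
# blood + two liver lobes per individual, with age-dependent heteroplasmy
# counts, recurrent liver sites, tunable between-lobe sharing, private
# haplotype variants, binomial read sampling and sequencing error.

#' Configuration of the synthetic cohort
#'
#' Defaults emulate the autopsy cohort the analysis assumes: 83
#' individuals aged 24-94, one blood and two liver samples each, mean
#' depths 1,175x (blood) and 2,640x (liver), recurrent liver
#' heteroplasmies at control-region sites 60/72/94 (and the rarer common
#' sites), heteroplasmy counts increasing linearly with age, a Beta MAF
#' distribution with mean ~10.8%, and region-specific probabilities that
#' a liver heteroplasmy is present in both lobes (55% control / 7.5%
#' non-control, the observed shared fractions).
#'
#' @param n_individuals number of individuals (83).
#' @param age_range uniform age range in years (24-94).
#' @param depth named mean depths per tissue class, `c(blood=, liver=)`.
#' @param error_rate per-base sequencing error probability (0.001).
#' @param het_rate list with `control` and `noncontrol` elements, each
#'   `c(base=, per_year=)`: the per-individual count of distinct liver
#'   heteroplasmic sites in that region is Poisson(base + per_year*age).
#'   Defaults give cohort means of ~2.5 control and ~3.4 non-control
#'   sites per individual at the mean age.
#' @param blood_rate_factor multiplier on `het_rate` for blood (0.15).
#' @param recurrent_sites data.frame `pos`, `prob`, `tissue`,
#'   `shared_prob`: catalogue of recurrently heteroplasmic positions and
#'   their per-individual occurrence probabilities. Defaults include the
#'   frequent liver sites 60 (26/83), 72 (67/83) and 94 (20/83).
#' @param shared_fraction_control,shared_fraction_noncontrol probability
#'   that a (non-recurrent) liver heteroplasmy is present in both lobes.
#' @param maf_shape Beta(shape1, shape2) for the true MAF; the default
#'   (2, 16.5) has mean 0.108.
#' @param lobe_maf_jitter sd of the truncated-Gaussian difference between
#'   the two lobes' true MAFs at shared sites (0.02).
#' @param n_private_variants Poisson mean of homoplasmic private
#'   (haplotype) variants per individual (25).
#' @param n_background number of shared no-heteroplasmy background
#'   positions emitted per sample (300).
#' @param seed integer RNG seed; identical seeds give identical cohorts.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_individuals = 83L,
                          age_range = c(24, 94),
                          depth = c(blood = 1175, liver = 2640),
                          error_rate = 0.001,
                          het_rate = list(
                            control = c(base = 0.5, per_year = 0.034),
                            noncontrol = c(base = 0.3, per_year = 0.052)),
                          blood_rate_factor = 0.15,
                          recurrent_sites = default_recurrent_sites(),
                          shared_fraction_control = 0.55,
                          shared_fraction_noncontrol = 0.075,
                          maf_shape = c(2, 16.5),
                          lobe_maf_jitter = 0.02,
                          n_private_variants = 25,
                          n_background = 300L,
                          seed = 1L) {
  stopifnot(n_individuals >= 1, all(depth > 0),
            error_rate >= 0, error_rate < 0.5,
            shared_fraction_control >= 0, shared_fraction_control <= 1,
            shared_fraction_noncontrol >= 0, shared_fraction_noncontrol <= 1,
            lobe_maf_jitter >= 0, all(maf_shape > 0))
  if (any(c(het_rate$control, het_rate$noncontrol) < 0))
    stop("heteroplasmy rates must be non-negative")
  structure(as.list(environment()), class = "cohort_config")
}

#' Default recurrent-site catalogue
#'
#' Occurrence probabilities follow the observed individual counts for the
#' frequent sites (67/83 at 72, 26/83 at 60, 20/83 at 94) and a 6/83
#' baseline for the remaining common sites.
#' @return data.frame `pos`, `prob`, `tissue`, `shared_prob`.
#' @export
default_recurrent_sites <- function() {
  data.frame(
    pos = c(60L, 72L, 94L, 185L, 189L, 203L, 11126L, 16093L, 16126L, 12705L),
    prob = c(26, 67, 20, 6, 6, 6, 6, 6, 6, 6) / 83,
    tissue = c(rep("liver", 9), "blood"),
    shared_prob = c(rep(0.8, 9), NA),
    stringsAsFactors = FALSE
  )
}

rtruncnorm01 <- function(n, mean, sd) {
  if (sd == 0) return(rep_len(mean, n))
  lo <- stats::pnorm(0, mean, sd); hi <- stats::pnorm(1, mean, sd)
  stats::qnorm(stats::runif(n, lo, hi), mean, sd)
}

# split a count vector into 3 equal-probability categories (vectorised)
split3 <- function(n) {
  a <- stats::rbinom(length(n), n, 1 / 3)
  b <- stats::rbinom(length(n), n - a, 1 / 2)
  cbind(a, b, n - a - b)
}

# Simulate strand-resolved counts for one sample at `pos` with consensus
# allele `major`, minor allele `minor` (NA where homoplasmic) and true
# minor fraction `maf`. Errors are drawn from consensus reads and spread
# uniformly over the three non-consensus alleles.
simulate_counts <- function(pos, ref, major, minor, maf, mean_depth,
                            error_rate) {
  n <- length(pos)
  depth <- stats::rpois(n, mean_depth)
  depth[depth == 0L] <- 1L
  k_minor <- ifelse(is.na(minor), 0L, stats::rbinom(n, depth, maf))
  k_major <- depth - k_minor
  err <- stats::rbinom(n, k_major, error_rate)
  k_major <- k_major - err
  errsplit <- split3(err)
  tot <- matrix(0L, n, 4L, dimnames = list(NULL, BASES))
  tot[cbind(seq_len(n), match(major, BASES))] <- k_major
  midx <- match(minor, BASES)
  has_minor <- !is.na(midx)
  tot[cbind(which(has_minor), midx[has_minor])] <-
    tot[cbind(which(has_minor), midx[has_minor])] + k_minor[has_minor]
  # error targets: the three alleles other than the consensus
  other <- matrix(0L, n, 3L)
  for (j in 1:4) {
    rows <- which(match(major, BASES) == j)
    if (!length(rows)) next
    cols <- setdiff(1:4, j)
    tot[rows, cols] <- tot[rows, cols] + errsplit[rows, , drop = FALSE]
  }
  fwd <- matrix(stats::rbinom(4L * n, as.vector(tot), 0.5), n, 4L)
  rev <- tot - fwd
  out <- data.frame(pos = pos, ref = ref, stringsAsFactors = FALSE)
  for (j in 1:4) out[[paste0(BASES[j], "_fwd")]] <- fwd[, j]
  for (j in 1:4) out[[paste0(BASES[j], "_rev")]] <- rev[, j]
  out
}

#' Generate a synthetic autopsy cohort
#'
#' Draws ages, private haplotype variants, true heteroplasmies (with the
#' configured region-specific sharing between liver lobes) and then
#' strand-resolved read counts for every individual x tissue sample.
#' Counts are emitted for a panel of positions: a shared background set,
#' every private variant position of the whole cohort (so contamination
#' screens have signal) and each individual's true heteroplasmic sites.
#'
#' @param config a [cohort_config()].
#' @param genome a [mito_genome()].
#' @return object of class `het_cohort`: list with `counts` (long
#'   data.frame: sample, individual, tissue, pos, ref, A_fwd..T_rev),
#'   `truth` (one row per true heteroplasmy per tissue), `ages`,
#'   `samples` (sample metadata incl. mean depth), `consensus` (per
#'   individual data.frame pos/consensus over its panel), `config`,
#'   `genome`.
#' @export
generate_cohort <- function(config = cohort_config(), genome = mito_genome()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  map <- genome$map %||% region_map()
  n <- config$n_individuals
  inds <- sprintf("ind%03d", seq_len(n))
  ages <- round(stats::runif(n, config$age_range[1], config$age_range[2]))

  allowed <- setdiff(seq_len(genome$length), map$excluded)
  ctrl_pool <- setdiff(intersect(allowed, map$control), config$recurrent_sites$pos)
  nc_pool <- setdiff(intersect(allowed, map$noncontrol), config$recurrent_sites$pos)
  background <- sort(sample(allowed, min(config$n_background, length(allowed))))

  # private homoplasmic haplotype variants
  private <- lapply(seq_len(n), function(i) {
    k <- stats::rpois(1L, config$n_private_variants)
    p <- sort(sample(setdiff(allowed, background), k))
    data.frame(pos = p,
               allele = random_alt(genome$seq[p]),
               stringsAsFactors = FALSE)
  })
  names(private) <- inds
  panel_core <- sort(unique(c(background, unlist(lapply(private, `[[`, "pos")))))

  truth <- vector("list", n)
  for (i in seq_len(n)) {
    truth[[i]] <- draw_individual_truth(inds[i], ages[i], config, genome,
                                        map, ctrl_pool, nc_pool,
                                        private[[i]]$pos)
  }
  truth <- do.call(rbind, truth)

  tissues <- c("blood", "liver1", "liver2")
  counts <- vector("list", n * 3L)
  samples <- vector("list", n * 3L)
  k <- 0L
  for (i in seq_len(n)) {
    own_het <- sort(unique(truth$pos[truth$individual == inds[i]]))
    panel <- sort(unique(c(panel_core, own_het)))
    cons <- genome$seq[panel]
    pm <- match(private[[i]]$pos, panel)
    cons[pm] <- private[[i]]$allele
    for (tis in tissues) {
      k <- k + 1L
      tr <- truth[truth$individual == inds[i] & truth$tissue == tis, ,
                  drop = FALSE]
      minor <- rep(NA_character_, length(panel))
      maf <- rep(0, length(panel))
      tm <- match(tr$pos, panel)
      minor[tm] <- tr$minor
      maf[tm] <- tr$true_maf
      md <- unname(config$depth[tissue_class(tis)])
      tab <- simulate_counts(panel, genome$seq[panel], cons, minor, maf,
                             md, config$error_rate)
      tab <- cbind(sample = paste(inds[i], tis, sep = "_"),
                   individual = inds[i], tissue = tis, tab,
                   stringsAsFactors = FALSE)
      counts[[k]] <- tab
      samples[[k]] <- data.frame(sample = tab$sample[1], individual = inds[i],
                                 tissue = tis, mean_depth = md,
                                 stringsAsFactors = FALSE)
    }
  }
  consensus <- lapply(seq_len(n), function(i) {
    own_het <- sort(unique(truth$pos[truth$individual == inds[i]]))
    panel <- sort(unique(c(panel_core, own_het)))
    cons <- genome$seq[panel]
    cons[match(private[[i]]$pos, panel)] <- private[[i]]$allele
    data.frame(pos = panel, consensus = cons, stringsAsFactors = FALSE)
  })
  names(consensus) <- inds

  structure(list(
    counts = do.call(rbind, counts),
    truth = truth,
    ages = data.frame(individual = inds, age = ages, stringsAsFactors = FALSE),
    samples = do.call(rbind, samples),
    consensus = consensus,
    private = private,
    config = config,
    genome = genome
  ), class = "het_cohort")
}

random_alt <- function(ref) {
  vapply(ref, function(b) sample(setdiff(BASES, b), 1L), character(1),
         USE.NAMES = FALSE)
}

# All true heteroplasmy records for one individual (all three tissues).
draw_individual_truth <- function(ind, age, config, genome, map,
                                  ctrl_pool, nc_pool, private_pos) {
  rec <- config$recurrent_sites
  events <- list()

  liver_events <- function(region, pool, shared_frac) {
    rate <- config$het_rate[[region]]
    n_ev <- stats::rpois(1L, rate["base"] + rate["per_year"] * age)
    n_ev <- min(n_ev, length(pool))
    if (n_ev == 0L) return(NULL)
    data.frame(pos = sample(pool, n_ev), region = region,
               shared_prob = shared_frac, tissue_set = "liver",
               stringsAsFactors = FALSE)
  }
  events$lc <- liver_events("control", setdiff(ctrl_pool, private_pos),
                            config$shared_fraction_control)
  events$ln <- liver_events("noncontrol", setdiff(nc_pool, private_pos),
                            config$shared_fraction_noncontrol)

  recl <- rec[rec$tissue == "liver", , drop = FALSE]
  if (nrow(recl)) {
    hit <- stats::runif(nrow(recl)) < recl$prob
    if (any(hit)) {
      rr <- recl[hit, , drop = FALSE]
      events$rec <- data.frame(
        pos = rr$pos,
        region = classify_region(rr$pos, map)$region,
        shared_prob = rr$shared_prob, tissue_set = "liver",
        stringsAsFactors = FALSE)
    }
  }

  # blood: scaled-down rates plus the blood recurrent sites
  brate <- config$blood_rate_factor
  blood_events <- function(region, pool) {
    rate <- config$het_rate[[region]]
    n_ev <- stats::rpois(1L, brate * (rate["base"] + rate["per_year"] * age))
    n_ev <- min(n_ev, length(pool))
    if (n_ev == 0L) return(NULL)
    data.frame(pos = sample(pool, n_ev), region = region,
               shared_prob = NA_real_, tissue_set = "blood",
               stringsAsFactors = FALSE)
  }
  events$bc <- blood_events("control", setdiff(ctrl_pool, private_pos))
  events$bn <- blood_events("noncontrol", setdiff(nc_pool, private_pos))
  recb <- rec[rec$tissue == "blood", , drop = FALSE]
  if (nrow(recb)) {
    hit <- stats::runif(nrow(recb)) < recb$prob
    if (any(hit)) {
      rb <- recb[hit, , drop = FALSE]
      events$recb <- data.frame(
        pos = rb$pos, region = classify_region(rb$pos, map)$region,
        shared_prob = NA_real_, tissue_set = "blood",
        stringsAsFactors = FALSE)
    }
  }

  ev <- do.call(rbind, events)
  if (is.null(ev) || nrow(ev) == 0L) return(NULL)
  ev <- ev[!duplicated(paste(ev$pos, ev$tissue_set)), , drop = FALSE]

  out <- vector("list", nrow(ev))
  eff <- effect_matrix(genome)
  for (j in seq_len(nrow(ev))) {
    pos <- ev$pos[j]
    minor <- random_alt(genome$seq[pos])
    m <- stats::rbeta(1L, config$maf_shape[1], config$maf_shape[2])
    lab <- c("non-coding", "synonymous", "non-synonymous")[
      eff[pos, match(minor, BASES)] + 1L]
    if (ev$tissue_set[j] == "blood") {
      out[[j]] <- data.frame(individual = ind, tissue = "blood", pos = pos,
                             region = ev$region[j], minor = minor,
                             true_maf = m, shared = FALSE, label = lab,
                             stringsAsFactors = FALSE)
    } else {
      shared <- stats::runif(1L) < ev$shared_prob[j]
      if (shared) {
        m2 <- rtruncnorm01(1L, m, config$lobe_maf_jitter)
        tis <- c("liver1", "liver2"); mafs <- c(m, m2)
      } else {
        tis <- sample(c("liver1", "liver2"), 1L); mafs <- m
      }
      out[[j]] <- data.frame(individual = ind, tissue = tis, pos = pos,
                             region = ev$region[j], minor = minor,
                             true_maf = mafs, shared = shared, label = lab,
                             stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' @export
print.het_cohort <- function(x, ...) {
  cat("<het_cohort> ", nrow(x$ages), " individuals, ",
      nrow(x$samples), " samples, ",
      nrow(x$truth), " true heteroplasmy records\n", sep = "")
  invisible(x)
}

#' Simulate full-genome coverage profiles
#'
#' Per-position Poisson depth around each sample's mean; used by the
#' sample QC and the D-loop coverage comparison.
#'
#' @param cohort a `het_cohort`.
#' @param samples optional subset of sample ids.
#' @return integer matrix, genome length x samples.
#' @export
simulate_coverage <- function(cohort, samples = cohort$samples$sample) {
  L <- cohort$genome$length
  idx <- match(samples, cohort$samples$sample)
  m <- vapply(idx, function(i)
    stats::rpois(L, cohort$samples$mean_depth[i]), integer(L))
  colnames(m) <- samples
  m
}

#' Inject cross-sample contamination
#'
#' Mixes a donor sample into a recipient: at every recipient panel
#' position also present in the donor, the expected allele fractions
#' become `(1-fraction) * recipient + fraction * donor`, and counts are
#' re-sampled binomially at the recipient's depth per strand.
#'
#' @param cohort a `het_cohort`.
#' @param donor_sample,recipient_sample sample ids.
#' @param fraction contamination fraction, in (0, 0.5).
#' @return modified cohort.
#' @export
inject_contamination <- function(cohort, donor_sample, recipient_sample,
                                 fraction) {
  if (!(fraction > 0 && fraction < 0.5))
    stop("fraction must be in (0, 0.5)")
  cts <- cohort$counts
  don <- cts[cts$sample == donor_sample, , drop = FALSE]
  rec <- cts[cts$sample == recipient_sample, , drop = FALSE]
  if (!nrow(don) || !nrow(rec)) stop("unknown sample id")
  dcons <- consensus_alleles(don)
  rcons <- consensus_alleles(rec)
  shared <- intersect(don$pos, rec$pos)
  if (!any(dcons$consensus[match(shared, dcons$pos)] !=
           rcons$consensus[match(shared, rcons$pos)]))
    stop("donor and recipient have identical consensus at every shared site")

  dm <- count_matrices(don[match(shared, don$pos), , drop = FALSE])
  rm_ <- count_matrices(rec[match(shared, rec$pos), , drop = FALSE])
  dfrac <- dm$tot / pmax(rowSums(dm$tot), 1)
  for (strand in c("fwd", "rev")) {
    sm <- rm_[[strand]]
    sd_ <- rowSums(sm)
    p <- (1 - fraction) * sm / pmax(sd_, 1) + fraction * dfrac
    new <- matrix(0L, nrow(sm), 4L)
    rem_n <- sd_
    rem_p <- rowSums(p)
    for (j in 1:3) {
      pj <- ifelse(rem_p > 0, pmin(p[, j] / rem_p, 1), 0)
      new[, j] <- stats::rbinom(nrow(sm), rem_n, pj)
      rem_n <- rem_n - new[, j]
      rem_p <- rem_p - p[, j]
    }
    new[, 4L] <- rem_n
    cols <- paste0(BASES, "_", strand)
    rows <- which(cts$sample == recipient_sample)[match(shared, rec$pos)]
    cts[rows, cols] <- new
  }
  cohort$counts <- cts
  cohort
}
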