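# End-to-end orchestration: simulate -> QC -> call -> contamination
# screens -> sharing statistics -> drift -> selection -> report.

#' Call heteroplasmies for a whole cohort
#'
#' Computes per-individual blood major alleles (the blood consensus) and
#' runs the filter cascade on every sample. Optionally runs the two
#' contamination screens across individuals (pairwise liver-vs-liver and
#' blood-vs-blood, then the haplogroup-excess rule) and drops flagged
#' individuals.
#'
#' @param cohort a `het_cohort` (or any list with `counts`, `samples`,
#'   `genome` of the same shape).
#' @param config a [filter_config()].
#' @param screens run the contamination screens (they scale with the
#'   square of the cohort; disable for speed when no contamination is
#'   simulated).
#' @return list: `calls` (long data.frame over retained individuals,
#'   passed and failed sites), `dropped` (individual -> reason),
#'   `screen` (diagnostics) .
#' @export
call_cohort <- function(cohort, config = filter_config(), screens = TRUE) {
  counts <- cohort$counts
  samples <- cohort$samples
  map <- cohort$genome$map %||% region_map()
  inds <- unique(samples$individual)

  calls <- vector("list", nrow(samples))
  for (i in seq_len(nrow(samples))) {
    s <- samples$sample[i]; ind <- samples$individual[i]
    tis <- samples$tissue[i]
    tab <- counts[counts$sample == s, , drop = FALSE]
    blood <- counts[counts$individual == ind & counts$tissue == "blood", ,
                    drop = FALSE]
    if (!nrow(blood)) stop("missing blood sample for ", ind)
    bcons <- consensus_alleles(blood)
    bm <- bcons$consensus[match(tab$pos, bcons$pos)]
    if (any(is.na(bm))) bm[is.na(bm)] <- tab$ref[is.na(bm)]
    cl <- call_sample(tab, bm, tis, samples$mean_depth[i], config, map)
    cl <- cbind(sample = s, individual = ind, cl, stringsAsFactors = FALSE)
    calls[[i]] <- cl
  }
  calls <- do.call(rbind, calls)

  dropped <- character()
  screen <- NULL
  if (screens) {
    screen <- contamination_screen_cohort(cohort, calls, config)
    dropped <- screen$dropped
    if (length(dropped))
      calls <- calls[!calls$individual %in% dropped, , drop = FALSE]
  }
  list(calls = calls, dropped = dropped, screen = screen)
}

# Cohort-wide contamination screening on the shared position panel.
contamination_screen_cohort <- function(cohort, calls, config) {
  counts <- cohort$counts
  samples <- cohort$samples
  panel <- Reduce(intersect, split(counts$pos, counts$sample))
  panel <- sort(panel)
  ns <- nrow(samples)
  cons <- minor <- matrix(NA_character_, length(panel), ns)
  maf <- matrix(NA_real_, length(panel), ns)
  frac_called <- numeric(ns)
  for (i in seq_len(ns)) {
    tab <- counts[counts$sample == samples$sample[i], , drop = FALSE]
    tab <- tab[match(panel, tab$pos), , drop = FALSE]
    cc <- consensus_alleles(tab)
    mm <- compute_maf(tab, cc$consensus)
    cons[, i] <- cc$consensus
    minor[, i] <- mm$minor
    maf[, i] <- mm$maf
    smp_calls <- calls[calls$sample == samples$sample[i], , drop = FALSE]
    has_minor <- mm$pos[mm$maf > 0]
    frac_called[i] <- if (length(has_minor))
      mean(has_minor %in% smp_calls$pos[smp_calls$pass]) else NA_real_
  }
  th <- config$contamination
  flagged_pairs <- list()
  flagged_inds <- character()
  for (i in seq_len(ns)) for (j in seq_len(ns)) {
    if (i == j) next
    if (samples$individual[i] == samples$individual[j]) next
    if (tissue_class(samples$tissue[i]) != tissue_class(samples$tissue[j])) next
    d <- cons[, i] != cons[, j]
    if (!any(d)) next
    c1 <- mean(minor[d, i] == cons[d, j])
    c2 <- mean(maf[d, i])
    c3 <- frac_called[i]
    if (isTRUE(c1 >= th$min_frac_donor_major) &&
        isTRUE(c2 >= th$min_mean_maf) &&
        isTRUE(c3 >= th$min_frac_called)) {
      flagged_pairs[[length(flagged_pairs) + 1L]] <-
        data.frame(recipient = samples$sample[i], donor = samples$sample[j],
                   frac_donor_major = c1, mean_maf = c2, frac_called = c3,
                   stringsAsFactors = FALSE)
      flagged_inds <- union(flagged_inds, samples$individual[i])
    }
  }
  # haplogroup-excess rule
  for (ind in unique(samples$individual)) {
    ind_calls <- calls[calls$individual == ind & calls$pass, , drop = FALSE]
    if (!nrow(ind_calls)) next
    own_i <- which(samples$individual == ind)[1]
    pm <- match(ind_calls$pos, panel)
    ok <- !is.na(pm)
    if (!any(ok)) next
    own <- cons[pm[ok], own_i]
    best <- 0L
    for (j in seq_len(ns)) {
      if (samples$individual[j] == ind) next
      dc <- cons[pm[ok], j]
      best <- max(best, sum(dc != own & dc == ind_calls$minor[ok]))
    }
    if (best >= config$haplogroup_min_sites)
      flagged_inds <- union(flagged_inds, ind)
  }
  list(dropped = flagged_inds,
       pairs = if (length(flagged_pairs)) do.call(rbind, flagged_pairs)
       else NULL)
}

#' Sharing analysis of a called cohort
#'
#' Builds liver1-vs-liver2 MAF pairs, the shared x region 2x2 table with
#' Fisher's exact test and shared fractions, Pearson correlations with
#' permutation p (overall / control / non-control), the random-partition
#' test for the difference in r, the subsampling test for the recurrent
#' sites, and the |delta MAF| vs age correlations. P-values of the
#' correlation family are Benjamini-Hochberg adjusted.
#'
#' @param calls long call table from [call_cohort()].
#' @param ages data.frame `individual`, `age`.
#' @param map a `region_map`.
#' @param recurrent_pos target sites of the subsampling test (60/72/94).
#' @param n_perm permutations per test (1000).
#' @param seed RNG seed.
#' @return list of results (see components).
#' @export
share_analysis <- function(calls, ages, map = region_map(),
                           recurrent_pos = c(60L, 72L, 94L),
                           n_perm = 1000L, seed = 1L) {
  l1 <- calls[calls$tissue == "liver1", , drop = FALSE]
  l2 <- calls[calls$tissue == "liver2", , drop = FALSE]
  pairs <- build_maf_pairs(l1, l2, map)
  if (nrow(pairs) < 3L) stop("too few liver MAF pairs")
  is_ctrl <- pairs$region == "control"
  tab <- matrix(c(sum(pairs$shared & is_ctrl), sum(!pairs$shared & is_ctrl),
                  sum(pairs$shared & !is_ctrl), sum(!pairs$shared & !is_ctrl)),
                2L, 2L, dimnames = list(c("shared", "not_shared"),
                                        c("control", "noncontrol")))
  res <- list(pairs = pairs, table = tab,
              fisher_p = sharing_fisher(tab),
              shared_fraction = c(control = shared_fraction(tab, "control"),
                                  noncontrol = shared_fraction(tab, "noncontrol"),
                                  overall = 100 * sum(tab[1, ]) / sum(tab)))
  res$r_all <- pearson_r_perm(pairs, n_perm = n_perm, seed = seed)
  if (sum(is_ctrl) >= 3L)
    res$r_control <- pearson_r_perm(pairs[is_ctrl, ], n_perm = n_perm,
                                    seed = seed + 1L)
  if (sum(!is_ctrl) >= 3L)
    res$r_noncontrol <- pearson_r_perm(pairs[!is_ctrl, ], n_perm = n_perm,
                                       seed = seed + 2L)
  if (sum(is_ctrl) > 0L && sum(!is_ctrl) > 0L)
    res$partition <- partition_permutation_test(pairs, is_ctrl,
                                                n_perm = n_perm,
                                                seed = seed + 3L)
  ctrl_pairs <- pairs[is_ctrl, , drop = FALSE]
  tgt <- ctrl_pairs$pos %in% recurrent_pos
  if (any(tgt) && sum(is_ctrl) >= 3L)
    res$subsample <- subsample_correlation_test(ctrl_pairs, tgt,
                                                n_perm = n_perm,
                                                seed = seed + 4L)
  shared_pairs <- pairs[pairs$shared, , drop = FALSE]
  if (!is.null(ages) && nrow(shared_pairs) >= 3L) {
    sc <- shared_pairs[shared_pairs$region == "control", , drop = FALSE]
    sn <- shared_pairs[shared_pairs$region == "noncontrol", , drop = FALSE]
    if (nrow(sc) >= 3L)
      res$dmaf_age_control <- maf_diff_vs_age(sc, ages, n_perm = n_perm,
                                              seed = seed + 5L)
    if (nrow(sn) >= 3L)
      res$dmaf_age_noncontrol <- maf_diff_vs_age(sn, ages, n_perm = n_perm,
                                                 seed = seed + 6L)
  }
  ps <- c(r_all = res$r_all$p_perm,
          r_control = if (!is.null(res$r_control)) res$r_control$p_perm,
          r_noncontrol = if (!is.null(res$r_noncontrol)) res$r_noncontrol$p_perm,
          dmaf_age_control = if (!is.null(res$dmaf_age_control))
            res$dmaf_age_control$p_perm,
          dmaf_age_noncontrol = if (!is.null(res$dmaf_age_noncontrol))
            res$dmaf_age_noncontrol$p_perm)
  res$p_adjusted <- stats::setNames(bh_adjust(unname(ps)), names(ps))
  res
}

#' Run configuration for the full pipeline
#'
#' @param cohort a [cohort_config()].
#' @param filter a [filter_config()].
#' @param drift a [drift_config()].
#' @param n_perm permutations for all resampling tests.
#' @param seed global seed; stage seeds are derived deterministically.
#' @param screens run the contamination screens.
#' @param copy_ratio depth-to-copy-number calibration used when matching
#'   the drift grid. The synthetic generator's depth stands directly for
#'   relative mtDNA abundance, so the default is 1 (liver depth 2,640
#'   maps near the 2,500-copy grid cell); capture-enrichment relative
#'   coverage uses 1/150 (see [relative_copy_number()]).
#' @return list of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config(), filter = filter_config(),
                       drift = drift_config(), n_perm = 1000L, seed = 1L,
                       screens = TRUE, copy_ratio = 1) {
  structure(list(cohort = cohort, filter = filter, drift = drift,
                 n_perm = as.integer(n_perm), seed = as.integer(seed),
                 screens = isTRUE(screens), copy_ratio = copy_ratio),
            class = "run_config")
}

stage_seed <- function(seed, stage) (seed * 7L + stage * 1009L) %% 2147483647L

#' Run the full pipeline on a synthetic cohort
#'
#' simulate -> coverage QC -> call (+ contamination screens) -> sharing
#' statistics -> drift grid + variance F-test -> hN/hS selection ->
#' report. Every stage is seeded deterministically from the global seed.
#'
#' @param config a [run_config()].
#' @param out optional output directory; when given, calls, tables and
#'   the JSON report are written there.
#' @return list: `cohort`, `calls`, `qc`, `share`, `drift`, `selection`,
#'   `report`.
#' @export
run_pipeline <- function(config = run_config(), out = NULL) {
  stopifnot(inherits(config, "run_config"))
  cc <- config$cohort
  cc$seed <- stage_seed(config$seed, 1L)
  cohort <- generate_cohort(cc)

  set.seed(stage_seed(config$seed, 2L))
  coverage <- simulate_coverage(cohort)
  qc <- lapply(seq_len(ncol(coverage)), function(i)
    sample_qc(coverage[, i], config$filter))
  names(qc) <- colnames(coverage)
  bad_samples <- names(qc)[!vapply(qc, `[[`, logical(1), "keep")]
  bad_inds <- unique(cohort$samples$individual[
    cohort$samples$sample %in% bad_samples])
  if (length(bad_inds)) {
    keep <- !cohort$samples$individual %in% bad_inds
    cohort$samples <- cohort$samples[keep, , drop = FALSE]
    cohort$counts <- cohort$counts[!cohort$counts$individual %in% bad_inds, ,
                                   drop = FALSE]
  }

  called <- call_cohort(cohort, config$filter, screens = config$screens)
  passed <- called$calls[called$calls$pass, , drop = FALSE]

  share <- share_analysis(called$calls, cohort$ages,
                          map = cohort$genome$map %||% region_map(),
                          n_perm = config$n_perm,
                          seed = stage_seed(config$seed, 3L))

  dcfg <- config$drift
  dcfg$seed <- stage_seed(config$seed, 4L)
  grid <- run_grid(dcfg)
  cn <- mean(vapply(seq_len(ncol(coverage)), function(i)
    relative_copy_number(coverage[, i], config$copy_ratio), numeric(1))[
      cohort$samples$tissue != "blood"])
  shared_pairs <- share$pairs[share$pairs$shared, , drop = FALSE]
  drift_res <- list(grid_summary = grid$summary, mean_copy_number = cn)
  if (nrow(shared_pairs) >= 2L) {
    cell <- select_matching_cell(grid, cn, mean(shared_pairs$maf_a))
    obs <- abs(shared_pairs$maf_a - shared_pairs$maf_b)
    gsel <- as.character(min(dcfg$generations[dcfg$generations >= 50L],
                             max(dcfg$generations)))
    sim <- grid$cells[[cell$key]][, gsel]
    drift_res <- c(drift_res, list(
      cell = cell, generation = as.integer(gsel),
      f_test = variance_f_test(obs, sim)))
  }

  genome <- cohort$genome
  liver_calls <- passed[passed$tissue != "blood", , drop = FALSE]
  sel_input <- share$pairs[, c("individual", "pos")]
  sel_input$minor <- liver_calls$minor[
    match(paste(sel_input$individual, sel_input$pos),
          paste(liver_calls$individual, liver_calls$pos))]
  sel_input$shared <- share$pairs$shared
  sel_input <- sel_input[!is.na(sel_input$minor), , drop = FALSE]
  cls <- classify_heteroplasmies(sel_input, genome)
  selection <- list(table = cls$table)
  coding <- cls$calls[cls$calls$label != "non-coding", , drop = FALSE]
  if (!is.null(cls$table) && sum(cls$table) > 0)
    selection$fisher_p <- sharing_fisher(cls$table)
  if (nrow(coding) && sum(cls$calls$label == "synonymous") > 0) {
    selection$hnhs <- hn_hs(coding, genome)
    selection$perm <- hn_hs_permutation_null(
      coding, genome, n_perm = config$n_perm,
      seed = stage_seed(config$seed, 5L))
  }
  if (nrow(coding) >= 2L)
    selection$age_groups <- tryCatch(
      age_group_counts(coding, cohort$ages, genome),
      error = function(e) NULL)

  report <- list(
    seed = config$seed,
    config_hash = config_hash(config),
    n_individuals = length(unique(cohort$samples$individual)),
    dropped_low_coverage = bad_inds,
    dropped_contamination = called$dropped,
    n_calls = nrow(passed),
    sharing_table = as.vector(share$table),
    fisher_p = share$fisher_p,
    shared_fraction = as.list(share$shared_fraction),
    r_all = share$r_all$r, r_all_p = share$r_all$p_perm,
    partition_p = if (!is.null(share$partition)) share$partition$p_perm,
    hnhs_ratio = if (!is.null(selection$hnhs)) selection$hnhs$ratio,
    hnhs_p = if (!is.null(selection$perm)) selection$perm$p_perm,
    drift_f_p = if (!is.null(drift_res$f_test)) drift_res$f_test$p
  )

  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    write_tsv(called$calls, file.path(out, "calls.tsv"))
    write_tsv(share$pairs, file.path(out, "maf_pairs.tsv"))
    write_tsv(grid$summary, file.path(out, "drift_summary.tsv"))
    write_json_report(report, file.path(out, "report.json"))
  }

  list(cohort = cohort, calls = called$calls, qc = qc, share = share,
       drift = drift_res, selection = selection, report = report)
}

config_hash <- function(config) {
  s <- paste(utils::capture.output(utils::str(config)), collapse = "\n")
  # small stable polynomial hash; avoids a digest dependency
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", h)
}
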