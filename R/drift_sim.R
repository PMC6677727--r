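# Two-step random genetic drift simulator for mtDNA segregation: at each
# cell division all molecules are partitioned equally (hypergeometric)
# into two daughters, which then replicate every molecule once to regain
# the parental copy number. All drift comes from the segregation step.

#' Drift simulation grid configuration
#'
#' Defaults are the canonical grid: copy numbers 1,000 / 2,500 / 5,000
#' (constant through the simulation), initial MAFs 5 / 10 / 20 / 50%,
#' MAF differences sampled 10, 20, 50, 100 and 250 generations after the
#' split, 1,000 replicates per cell.
#'
#' @param copy_numbers even mtDNA copy numbers N.
#' @param initial_mafs initial minor allele fractions in 0..0.5.
#' @param generations generations (divisions since the progenitor split)
#'   at which |delta MAF| is recorded.
#' @param replicates replicates per (N, p0) cell.
#' @param seed RNG seed.
#' @param replication "doubling" (deterministic, default) or "polya"
#'   (with-replacement resampling up to N, for sensitivity analysis).
#' @return list of class `drift_config`.
#' @export
drift_config <- function(copy_numbers = c(1000L, 2500L, 5000L),
                         initial_mafs = c(0.05, 0.10, 0.20, 0.50),
                         generations = c(10L, 20L, 50L, 100L, 250L),
                         replicates = 1000L,
                         seed = 1L,
                         replication = c("doubling", "polya")) {
  replication <- match.arg(replication)
  stopifnot(all(copy_numbers %% 2 == 0), all(copy_numbers >= 2),
            all(initial_mafs >= 0), all(initial_mafs <= 0.5),
            replicates >= 1, all(generations >= 1))
  structure(as.list(environment()), class = "drift_config")
}

#' One cell division
#'
#' The parent's `k` minor molecules (out of `N`) are segregated equally:
#' daughter 1 receives `k1 ~ Hypergeometric` of the minor molecules among
#' its N/2, daughter 2 the remaining `k - k1`. Each daughter then
#' replicates every molecule once, so the daughter minor counts are
#' `2 k1` and `2 (k - k1)` out of `N`.
#'
#' Vectorised over `k`.
#'
#' @param k minor-molecule counts (0..N).
#' @param N even copy number.
#' @param replication see [drift_config()].
#' @return matrix with columns `d1`, `d2` of daughter minor counts.
#' @export
divide_cell <- function(k, N, replication = "doubling") {
  if (N %% 2 != 0) stop("N must be even")
  stopifnot(all(k >= 0), all(k <= N))
  k1 <- stats::rhyper(length(k), m = k, n = N - k, k = N %/% 2L)
  k2 <- k - k1
  if (replication == "doubling") {
    cbind(d1 = 2L * k1, d2 = 2L * k2)
  } else {
    # Polya-style replication: sample N/2 additional molecules with
    # replacement from the daughter's N/2
    cbind(d1 = k1 + stats::rbinom(length(k1), N %/% 2L, k1 / (N / 2)),
          d2 = k2 + stats::rbinom(length(k2), N %/% 2L, k2 / (N / 2)))
  }
}

# advance one lineage (vector of minor counts) by one generation:
# divide and follow one random daughter
step_lineage <- function(k, N, replication = "doubling") {
  d <- divide_cell(k, N, replication)
  pick <- stats::runif(length(k)) < 0.5
  ifelse(pick, d[, 1L], d[, 2L])
}

#' Simulate MAF divergence between the two sides of a cell pedigree
#'
#' The progenitor cell starts with `round(p0 * N)` minor molecules. Its
#' first division creates the two sides of the pedigree (anti-correlated
#' by the shared segregation); each side then follows one random
#' daughter lineage per generation. At each requested generation t
#' (divisions since the split; t = 0 would be the two first daughters)
#' the absolute MAF difference between the two sides is recorded.
#'
#' @param N even copy number.
#' @param p0 initial minor fraction.
#' @param generations generations at which to record.
#' @param replicates number of independent pedigrees.
#' @param seed RNG seed (NULL: use current RNG state).
#' @param replication see [drift_config()].
#' @param return_counts also return the per-side minor counts.
#' @return matrix replicates x length(generations) of |delta MAF| (named
#'   by generation); with `return_counts`, a list with `dmaf`, `left`,
#'   `right`.
#' @export
simulate_pedigree_pair <- function(N, p0, generations = c(10L, 20L, 50L, 100L, 250L),
                                   replicates = 1000L, seed = NULL,
                                   replication = "doubling",
                                   return_counts = FALSE) {
  stopifnot(N %% 2 == 0, p0 >= 0, p0 <= 1, all(generations >= 1))
  if (!is.null(seed)) set.seed(seed)
  generations <- sort(unique(as.integer(generations)))
  k0 <- rep.int(as.integer(round(p0 * N)), replicates)
  first <- divide_cell(k0, N, replication)
  left <- first[, 1L]; right <- first[, 2L]
  dmaf <- matrix(NA_real_, replicates, length(generations),
                 dimnames = list(NULL, generations))
  lcnt <- rcnt <- matrix(NA_integer_, replicates, length(generations),
                         dimnames = list(NULL, generations))
  for (t in seq_len(max(generations))) {
    left <- step_lineage(left, N, replication)
    right <- step_lineage(right, N, replication)
    j <- match(t, generations)
    if (!is.na(j)) {
      dmaf[, j] <- abs(left - right) / N
      lcnt[, j] <- left; rcnt[, j] <- right
    }
  }
  if (return_counts) list(dmaf = dmaf, left = lcnt, right = rcnt) else dmaf
}

#' Run the full drift parameter grid
#'
#' @param config a [drift_config()].
#' @return list of class `drift_result`: `cells` (list keyed
#'   "N=..,p0=.." of |delta MAF| matrices), `summary` data.frame (N, p0,
#'   generation, mean, var), `config`.
#' @export
run_grid <- function(config = drift_config()) {
  set.seed(config$seed)
  cells <- list()
  rows <- list()
  for (N in config$copy_numbers) for (p0 in config$initial_mafs) {
    key <- sprintf("N=%d,p0=%g", N, p0)
    dm <- simulate_pedigree_pair(N, p0, config$generations,
                                 config$replicates,
                                 replication = config$replication)
    cells[[key]] <- dm
    rows[[key]] <- data.frame(
      N = N, p0 = p0, generation = as.integer(colnames(dm)),
      mean = colMeans(dm),
      var = apply(dm, 2L, stats::var),
      row.names = NULL)
  }
  structure(list(cells = cells, summary = do.call(rbind, c(rows, list(make.row.names = FALSE))),
                 config = config),
            class = "drift_result")
}

#' @export
print.drift_result <- function(x, ...) {
  cat("<drift_result> ", length(x$cells), " parameter cells x ",
      length(x$config$generations), " generations, ",
      x$config$replicates, " replicates\n", sep = "")
  invisible(x)
}

#' One-sided F-test: observed MAF differences less variable than drift
#'
#' Tests whether the variance of the observed between-lobe MAF
#' differences is smaller than the variance of simulated drift
#' differences. F = var(simulated) / var(observed), with upper-tail p
#' from the F distribution on (n_sim - 1, n_obs - 1) df.
#'
#' @param observed_diffs observed |delta MAF| vector.
#' @param simulated_diffs simulated |delta MAF| vector.
#' @return list: `F`, `df`, `p`.
#' @export
variance_f_test <- function(observed_diffs, simulated_diffs) {
  stopifnot(length(observed_diffs) >= 2, length(simulated_diffs) >= 2)
  v_o <- stats::var(observed_diffs); v_s <- stats::var(simulated_diffs)
  if (v_o == 0 || v_s == 0) stop("zero variance")
  F <- v_s / v_o
  df <- c(length(simulated_diffs) - 1L, length(observed_diffs) - 1L)
  list(F = F, df = df,
       p = stats::pf(F, df[1], df[2], lower.tail = FALSE))
}

#' Select the grid cell matching observed copy number and MAF
#'
#' Nearest cell by (|log N - log N_obs|, |p0 - MAF_obs|), compared
#' lexicographically (copy number decides first; the MAF breaks ties).
#'
#' @param grid a `drift_result` (or a `drift_config`).
#' @param copy_number observed mean copy number.
#' @param maf observed mean MAF of shared heteroplasmies.
#' @return list `N`, `p0`, `key`.
#' @export
select_matching_cell <- function(grid, copy_number, maf) {
  config <- if (inherits(grid, "drift_result")) grid$config else grid
  Ns <- config$copy_numbers; ps <- config$initial_mafs
  if (!length(Ns) || !length(ps)) stop("empty grid")
  dN <- abs(log(Ns) - log(copy_number))
  N_best <- Ns[which.min(dN)]
  dp <- abs(ps - maf)
  p_best <- ps[which.min(dp)]
  list(N = N_best, p0 = p_best, key = sprintf("N=%d,p0=%g", N_best, p_best))
}

#' Exact one-generation transition matrix of the daughter-lineage kernel
#'
#' State k (minor molecules of a followed daughter) moves to 2*k1 with
#' k1 ~ Hypergeometric(N, k, N/2). Used as the independent exact oracle
#' for small N.
#'
#' @param N even copy number.
#' @return (N+1) x (N+1) matrix, rows = current k (0..N).
#' @export
lineage_transition_matrix <- function(N) {
  stopifnot(N %% 2 == 0)
  P <- matrix(0, N + 1L, N + 1L)
  half <- N %/% 2L
  for (k in 0:N) {
    j <- 0:half
    P[k + 1L, 2L * j + 1L] <- stats::dhyper(j, k, N - k, half)
  }
  P
}
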