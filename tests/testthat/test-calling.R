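# MAF computation, quality score, filter cascade, QC, contamination

test_that("compute_maf does blood-oriented arithmetic", {
  expect_equal(compute_maf(make_counts(1, A = 1000), "A")$maf, 0)
  m <- compute_maf(make_counts(1, A = 900, G = 100), "A")
  expect_equal(m$minor, "G")
  expect_equal(m$maf, 0.10)
  expect_false(m$consensus_flip)
  # consensus flip: liver majority differs from blood major
  m2 <- compute_maf(make_counts(1, A = 300, G = 700), "A")
  expect_equal(m2$minor, "G")
  expect_equal(m2$maf, 0.70)
  expect_true(m2$consensus_flip)
  expect_error(compute_maf(make_counts(1), "A"), "zero depth")
})

test_that("minor-allele ties break by count then alphabet and are flagged", {
  m <- compute_maf(make_counts(1, A = 800, C = 100, G = 100), "A")
  expect_equal(m$minor, "C")
  expect_true(m$tie)
  m2 <- compute_maf(make_counts(1, A = 800, C = 90, G = 100), "A")
  expect_equal(m2$minor, "G")
  expect_false(m2$tie)
})

test_that("re-orienting to the tissue major flips MAF only at consensus flips", {
  set.seed(4)
  for (i in 1:40) {
    a <- sample(200:900, 1); g <- sample(200:900, 1)
    cts <- make_counts(1, A = a, G = g)
    blood <- compute_maf(cts, "A")
    tissue_major <- consensus_alleles(cts)$consensus
    local <- compute_maf(cts, tissue_major)
    if (blood$consensus_flip) expect_equal(local$maf, 1 - blood$maf)
    else expect_equal(local$maf, blood$maf)
  }
})

test_that("quality score equals an independent binomial tail summation", {
  oracle <- function(k, n, e) {
    p <- sum(dbinom(k:n, n, e))
    -10 * log10(p)
  }
  expect_equal(quality_score(0, 1000), 0)
  expect_equal(quality_score(50, 1000, 0.01), oracle(50, 1000, 0.01),
               tolerance = 1e-8)
  expect_equal(quality_score(3, 500, 0.001), oracle(3, 500, 0.001),
               tolerance = 1e-8)
  # monotone in minor count at fixed depth
  q <- quality_score(0:60, 1000, 0.01)
  expect_true(all(diff(q) >= 0))
  # cap applies
  expect_equal(quality_score(500, 1000, 0.001, cap = 99), 99)
})

make_ok_site <- function(pos = 5000, depth = 1000, maf = 0.1) {
  minor <- round(depth * maf / 2)
  make_counts(pos, A = depth - 2 * minor, G = 2 * minor,
              A_fwd = floor((depth - 2 * minor) / 2), G_fwd = minor)
}

test_that("filter cascade enforces each criterion with inclusive thresholds", {
  cfg <- filter_config()
  # all good
  cl <- call_sample(make_ok_site(), "A", "liver1", 1000, cfg)
  expect_true(cl$pass)
  expect_equal(cl$reasons, "")
  # depth 499 -> low_depth (and nothing else at 10% MAF)
  cl <- call_sample(make_ok_site(depth = 499, maf = 0.1), "A", "liver1",
                    499, cfg)
  expect_false(cl$pass)
  expect_match(cl$reasons, "low_depth")
  expect_false(grepl("low_maf", cl$reasons))
  # strand support 10/9
  cts <- make_counts(5000, A = 950, G = 19, A_fwd = 475, G_fwd = 10)
  cl <- call_sample(cts, "A", "liver1", 969, cfg)
  expect_match(cl$reasons, "strand_support")
  # common-site override waives only the quality criterion
  cts <- make_counts(72, A = 900, G = 100, A_fwd = 450, G_fwd = 50)
  cts$quality_fwd <- 3; cts$quality_rev <- 3
  cl <- call_sample(cts, "A", "liver1", 1000, cfg)
  expect_true(cl$pass)
  cl_blood <- call_sample(cts, "A", "blood", 1000, cfg)
  expect_false(cl_blood$pass)   # 72 is a liver common site only
  expect_match(cl_blood$reasons, "low_quality")
  # exact 2.5% boundary with 13/12 minor reads passes (inclusive)
  cts <- make_counts(5000, A = 975, G = 25, A_fwd = 507, G_fwd = 13)
  expect_equal(compute_maf(cts, "A")$maf_fwd, 13 / 520)
  cts$quality_fwd <- 15; cts$quality_rev <- 15
  cl <- call_sample(cts, "A", "liver1", 1000, cfg)
  expect_true(cl$pass)
  # excluded region
  cl <- call_sample(make_ok_site(pos = 310), "A", "liver1", 1000, cfg)
  expect_match(cl$reasons, "excluded_region")
  # coverage band: site at 2.5x the sample mean
  cl <- call_sample(make_ok_site(depth = 1000), "A", "liver1", 400, cfg)
  expect_match(cl$reasons, "coverage_band")
})

test_that("pass is a pure conjunction of the individual predicates", {
  cfg <- filter_config()
  set.seed(21)
  for (i in 1:50) {
    depth <- sample(300:1500, 1)
    maf <- runif(1, 0, 0.2)
    pos <- sample(c(310, 5000, 72), 1)
    minor <- round(depth * maf / 2)
    cts <- make_counts(pos, A = depth - 2 * minor, G = 2 * minor,
                       A_fwd = floor((depth - 2 * minor) / 2), G_fwd = minor)
    mean_depth <- sample(c(400, 1000), 1)
    cl <- call_sample(cts, "A", "liver1", mean_depth, cfg)
    m <- compute_maf(cts, "A")
    qf <- quality_score(m$minor_fwd, m$fwd_depth, cfg$error_rate)
    qr <- quality_score(m$minor_rev, m$rev_depth, cfg$error_rate)
    manual <- m$maf_fwd >= 0.025 && m$maf_rev >= 0.025 &&
      m$depth >= 500 && m$minor_fwd >= 10 && m$minor_rev >= 10 &&
      (pos %in% cfg$common_sites$liver || (qf >= 10 && qr >= 10)) &&
      !(pos %in% region_map()$excluded) &&
      m$depth >= 0.2 * mean_depth && m$depth <= 2 * mean_depth
    expect_equal(cl$pass, manual)
  }
})

test_that("sample QC drops on strictly more than 2% low coverage", {
  cfg <- filter_config()
  L <- 1000
  cov <- rep(1000, L)
  expect_true(sample_qc(cov, cfg)$keep)
  cov[1:20] <- 100     # exactly 2%
  expect_true(sample_qc(cov, cfg)$keep)
  cov[21:30] <- 100    # 3%
  qc <- sample_qc(cov, cfg)
  expect_false(qc$keep)
  expect_equal(qc$reason, "low_coverage_fraction")
  expect_error(sample_qc(cov, cfg, genome_length = 999), "length")
})

# toy contamination pair: `n_diff` sites with different consensus, of
# which a fraction carries donor-major minors in the recipient
contamination_fixture <- function(n_diff = 30, n_match = 27, maf = 0.02,
                                  frac_called = 0.7) {
  pos <- seq_len(n_diff)
  minor_cnt <- round(1000 * maf)
  rec <- do.call(rbind, lapply(pos, function(p) {
    if (p <= n_match) make_counts(p, A = 1000 - minor_cnt, G = minor_cnt)
    else make_counts(p, A = 1000 - minor_cnt, C = minor_cnt)
  }))
  don <- do.call(rbind, lapply(pos, function(p) make_counts(p, G = 1000)))
  n_called <- round(frac_called * n_diff)
  calls <- data.frame(pos = pos, pass = c(rep(TRUE, n_called),
                                          rep(FALSE, n_diff - n_called)))
  list(rec = rec, don = don, calls = calls)
}

test_that("pairwise contamination screen requires all three criteria", {
  f <- contamination_fixture()
  res <- pairwise_contamination_screen(f$rec, f$don, f$calls)
  expect_true(res$flagged)
  expect_equal(res$n_diff_sites, 30)
  expect_equal(res$frac_donor_major, 0.9)
  # mean MAF below 1% -> clear
  f2 <- contamination_fixture(maf = 0.005)
  expect_false(pairwise_contamination_screen(f2$rec, f2$don, f2$calls)$flagged)
  # under 80% donor-major matches -> clear
  f3 <- contamination_fixture(n_match = 20)
  expect_false(pairwise_contamination_screen(f3$rec, f3$don, f3$calls)$flagged)
  # under 60% of minor-bearing sites called -> clear
  f4 <- contamination_fixture(frac_called = 0.5)
  expect_false(pairwise_contamination_screen(f4$rec, f4$don, f4$calls)$flagged)
  # identical consensus everywhere -> vacuously clear
  res5 <- pairwise_contamination_screen(f$rec, f$rec, f$calls)
  expect_false(res5$flagged)
  expect_equal(res5$n_diff_sites, 0L)
})

test_that("haplogroup-excess rule drops at five jointly explained sites", {
  calls <- data.frame(pos = 1:6, minor = "G", pass = TRUE)
  own <- data.frame(pos = 1:6, consensus = "A")
  donor_match <- function(k) {
    data.frame(pos = 1:6, consensus = c(rep("G", k), rep("A", 6 - k)))
  }
  expect_true(haplogroup_excess_filter(calls, own,
                                       list(d = donor_match(4)))$keep)
  res <- haplogroup_excess_filter(calls, own, list(d = donor_match(5)))
  expect_false(res$keep)
  expect_equal(res$max_matching, 5L)
  expect_equal(res$best_donor, "d")
  expect_true(haplogroup_excess_filter(calls, own, list())$keep)
})

test_that("false-positive rate on a null cohort is below 1e-4 per site", {
  cfg <- cohort_config(
    n_individuals = 20, seed = 33,
    het_rate = list(control = c(base = 0, per_year = 0),
                    noncontrol = c(base = 0, per_year = 0)),
    recurrent_sites = data.frame(pos = integer(), prob = numeric(),
                                 tissue = character(),
                                 shared_prob = numeric()),
    n_private_variants = 0, n_background = 1500)
  co <- generate_cohort(cfg)
  called <- call_cohort(co, screens = FALSE)
  n_sites <- nrow(called$calls)
  expect_gt(n_sites, 50000)
  expect_lt(sum(called$calls$pass) / n_sites, 1e-4)
})

test_that("recompute_common_sites applies the five-individual rule", {
  calls <- data.frame(
    individual = c(paste0("i", 1:5), paste0("i", 1:4), "i1"),
    tissue = "liver1",
    pos = c(rep(100L, 5), rep(200L, 4), 300L),
    pass = TRUE)
  cs <- recompute_common_sites(calls)
  expect_equal(cs$liver, 100L)
})
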