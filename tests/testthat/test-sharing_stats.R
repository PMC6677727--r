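# MAF pairs, Fisher exact, permutation / partition / subsampling tests, BH

fake_calls <- function(individual, pos, maf, pass, tissue = "liver1") {
  data.frame(individual = individual, pos = pos, maf = maf, pass = pass,
             tissue = tissue, stringsAsFactors = FALSE)
}

test_that("build_maf_pairs keeps sites called in at least one tissue", {
  a <- fake_calls("i1", c(100L, 5000L, 300L), c(0.10, 0.008, 0.001),
                  c(TRUE, FALSE, FALSE))
  b <- fake_calls("i1", c(100L, 5000L, 300L), c(0.09, 0.05, 0.002),
                  c(TRUE, TRUE, FALSE), tissue = "liver2")
  p <- build_maf_pairs(a, b)
  expect_equal(sort(p$pos), c(100L, 5000L))
  p100 <- p[p$pos == 100L, ]
  expect_true(p100$shared)
  p200 <- p[p$pos == 5000L, ]
  expect_false(p200$shared)
  expect_equal(p200$maf_a, 0.008)   # raw MAF from the uncalled tissue
  expect_equal(p200$region, "noncontrol")
  # no calls anywhere -> empty
  none <- build_maf_pairs(fake_calls("i1", 1L, 0.001, FALSE),
                          fake_calls("i1", 1L, 0.001, FALSE))
  expect_equal(nrow(none), 0)
})

test_that("pearson_r_perm handles exact and degenerate cases", {
  x <- c(1, 2, 3, 4, 5)
  r <- pearson_r_perm(x, x, n_perm = 50, seed = 1)
  expect_equal(r$r, 1.0)
  expect_equal(pearson_r_perm(x, -x, n_perm = 50, seed = 1)$r, -1.0)
  expect_equal(r$p_perm, perm <- 1 / 51)
  expect_error(pearson_r_perm(x, rep(1, 5)), "constant")
  expect_error(pearson_r_perm(1:2, 2:1), "at least 3")
  # reproducible by seed
  set.seed(99); xx <- rnorm(30); yy <- rnorm(30)
  expect_identical(pearson_r_perm(xx, yy, n_perm = 99, seed = 7),
                   pearson_r_perm(xx, yy, n_perm = 99, seed = 7))
})

test_that("sharing_fisher equals stats::fisher.test over exhaustive small tables", {
  for (a in 0:6) for (b in 0:6) for (cc in 0:6) for (d in 0:6) {
    tab <- matrix(c(a, cc, b, d), 2)
    ours <- sharing_fisher(tab)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      expect_equal(ours, 1)
    } else {
      expect_equal(ours, stats::fisher.test(tab)$p.value, tolerance = 1e-10,
                   label = paste(a, b, cc, d))
    }
  }
  expect_equal(sharing_fisher(matrix(1, 2, 2)), 1.0)
})

test_that("shared_fraction reproduces the contingency-table percentages", {
  tab <- matrix(c(115, 95, 21, 260), 2,
                dimnames = list(c("shared", "not"), c("control", "noncontrol")))
  expect_equal(round(shared_fraction(tab, "control")), 55)
  expect_equal(round(shared_fraction(tab, "noncontrol"), 1), 7.5)
  expect_equal(shared_fraction(matrix(c(5, 0, 1, 0), 2), 1), 100)
  expect_error(shared_fraction(matrix(c(0, 0, 1, 1), 2), 1), "zero")
  # margin conservation: weighted category fractions recover the total
  f1 <- shared_fraction(tab, 1); f2 <- shared_fraction(tab, 2)
  tot <- (f1 * sum(tab[, 1]) + f2 * sum(tab[, 2])) / sum(tab)
  expect_equal(tot, 100 * sum(tab[1, ]) / sum(tab))
})

test_that("partition test finds a real correlation difference and rejects degenerate input", {
  set.seed(31)
  n <- 150
  g1 <- c(rep(TRUE, 70), rep(FALSE, 80))
  x <- runif(n, 0, 0.4)
  y <- ifelse(g1, x + rnorm(n, 0, 0.02), runif(n, 0, 0.4))
  pairs <- data.frame(maf_a = x, maf_b = pmax(y, 0))
  res <- partition_permutation_test(pairs, g1, n_perm = 199, seed = 3)
  expect_lt(res$p_perm, 0.02)
  expect_gt(res$delta_r, 0.5)
  expect_error(partition_permutation_test(pairs, rep(TRUE, n)), "degenerate")
})

test_that("subsample test: full-population target makes every draw identical", {
  set.seed(32)
  pairs <- data.frame(maf_a = runif(50), maf_b = runif(50))
  res <- subsample_correlation_test(pairs, rep(TRUE, 50), n_perm = 20, seed = 1)
  expect_true(all(res$null_r == res$r_target))
  expect_equal(res$p_perm, 1)
  expect_error(subsample_correlation_test(pairs, rep(FALSE, 50)), "no target")
})

test_that("subsample test near 0.5 for an unremarkable target subset", {
  set.seed(33)
  n <- 400
  x <- runif(n, 0, 0.4); y <- x + rnorm(n, 0, 0.05)
  pairs <- data.frame(maf_a = x, maf_b = y)
  tgt <- seq_len(n) %in% sample(n, 100)
  res <- subsample_correlation_test(pairs, tgt, n_perm = 400, seed = 2)
  expect_gt(res$p_perm, 0.05)
  expect_lt(res$p_perm, 0.95)
})

test_that("maf_diff_vs_age wiring and error paths", {
  ages <- data.frame(individual = paste0("i", 1:40), age = seq(25, 90, length.out = 40))
  set.seed(34)
  pairs <- data.frame(individual = rep(ages$individual, 2),
                      pos = rep(c(72L, 146L), each = 40),
                      maf_a = runif(80, 0.05, 0.3))
  pairs$maf_b <- pairs$maf_a + rnorm(80, 0, 0.02)
  res <- maf_diff_vs_age(pairs, ages, n_perm = 199, seed = 5)
  expect_s3_class(res, "correlation_result")
  expect_gt(res$p_perm, 0.01)   # age-independent jitter
  per <- maf_diff_vs_age(pairs, ages, per_site = TRUE, min_individuals = 20,
                         n_perm = 99, seed = 5)
  expect_setequal(names(per), c("72", "146"))
  # constant |dMAF| -> undefined correlation -> error
  pairs$maf_b <- pairs$maf_a
  expect_error(maf_diff_vs_age(pairs, ages, n_perm = 99), "constant")
  expect_error(maf_diff_vs_age(pairs[1:2, ], ages), "at least 3")
})

test_that("maf_diff_vs_age detects age-dependent divergence", {
  ages <- data.frame(individual = paste0("i", 1:150),
                     age = seq(25, 90, length.out = 150))
  set.seed(35)
  sdv <- 0.001 + 0.002 * ages$age
  pairs <- data.frame(individual = ages$individual, pos = 72L,
                      maf_a = runif(150, 0.05, 0.3))
  pairs$maf_b <- pairs$maf_a + rnorm(150, 0, sdv)
  res <- maf_diff_vs_age(pairs, ages, n_perm = 499, seed = 6)
  expect_gt(res$r, 0)
  expect_lt(res$p_perm, 0.05)
})

test_that("bh_adjust is the step-up procedure", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(rep(0.2, 4)), rep(0.2, 4))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(36)
  for (i in 1:20) {
    p <- runif(sample(1:15, 1))
    expect_equal(bh_adjust(p), stats::p.adjust(p, "BH"))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})
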