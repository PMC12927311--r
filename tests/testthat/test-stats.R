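test_that("rank-sum test matches its exact permutation oracle and base R", {
  # complete separation of 3 vs 3: exact two-sided p = 0.1
  rs <- rank_sum_test(1:3, 4:6)
  expect_equal(exact_rank_sum_p(1:3, 4:6), 0.1)
  expect_lt(rs$statistic, 0)                       # first sample smaller
  expect_equal(rs$p_value, 0.0809, tolerance = 1e-3)
  expect_lt(abs(rs$p_value - 0.1), 0.06)           # approximation gap
  # identical samples: exchangeable, p ~ 1
  expect_gt(rank_sum_test(c(1, 2, 3), c(1, 2, 3))$p_value, 0.8)
  expect_equal(rank_sum_test(rep(2, 4), rep(2, 5))$p_value, 1)
  # agreement with the tie- and continuity-corrected normal approximation
  # in stats::wilcox.test
  set.seed(41)
  for (i in 1:10) {
    x <- round(rnorm(7), 1); y <- round(rnorm(9, 0.5), 1)
    ours <- rank_sum_test(x, y)
    ref <- suppressWarnings(
      wilcox.test(x, y, exact = FALSE, correct = TRUE))
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("signed-rank test matches its exact sign-flip oracle and base R", {
  # all-positive differences 1..6: exact two-sided p = 2/64
  x <- c(10, 11, 12, 13, 14, 15); y <- x - (1:6)
  expect_equal(exact_signed_rank_p(x, y), 1 / 32)
  sr <- signed_rank_test(x, y)
  expect_gt(sr$statistic, 0)
  expect_equal(sr$p_value, 0.036, tolerance = 1e-3)
  # y = x: all differences zero
  expect_equal(signed_rank_test(x, x)$p_value, 1)
  # balanced antisymmetric differences: centered statistic
  xb <- c(1, 2, 3, 4); yb <- xb + c(-2, -1, 1, 2)
  expect_gt(signed_rank_test(xb, yb)$p_value, 0.8)
  set.seed(42)
  for (i in 1:10) {
    a <- round(rnorm(8), 1); b <- round(a + rnorm(8, 0.3), 1)
    keep <- a != b
    if (sum(keep) < 2) next
    ours <- signed_rank_test(a, b)
    ref <- suppressWarnings(
      wilcox.test(a[keep], b[keep], paired = TRUE, exact = FALSE,
                  correct = TRUE))
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("normal approximations track exhaustive oracles over small samples", {
  # property sweep over n1, n2 <= 8 with ties; documented approximation
  # bound 0.2 (computed supremum over a 4000-case sweep; typical gaps are
  # below 0.05 and fall to ~0.002 at the study's 42 + 38 sample sizes)
  set.seed(43)
  for (rep_i in 1:30) {
    n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
    x <- sample(1:6, n1, replace = TRUE)
    y <- sample(1:6, n2, replace = TRUE) + rnorm(1, 0, 0.5)
    p_exact <- exact_rank_sum_p(x, y)
    p_norm <- rank_sum_test(x, y)$p_value
    expect_lt(abs(p_norm - p_exact), 0.2)
  }
  for (rep_i in 1:30) {
    n <- sample(4:8, 1)
    a <- rnorm(n); b <- a + rnorm(n, 0.4)
    expect_lt(abs(signed_rank_test(a, b)$p_value -
                    exact_signed_rank_p(a, b)), 0.2)
  }
})

test_that("Bonferroni correction multiplies, caps, and preserves order", {
  expect_equal(bonferroni_correct(0.001, m = 31), 0.031)
  expect_equal(bonferroni_correct(0.5, m = 31), 1)
  expect_equal(bonferroni_correct(c(0.2, 0.7), m = 1), c(0.2, 0.7))
  p <- c(0.001, 0.01, 0.04, 0.2)
  pc <- bonferroni_correct(p, m = 31)
  expect_true(all(diff(pc) >= 0))
  expect_true(all(pc >= p))
})

test_that("Spearman correlation equals the rank-formula oracle", {
  expect_equal(spearman_cor(1:5, c(10, 20, 30, 40, 50))$rho, 1)
  expect_equal(spearman_cor(1:5, 5:1)$rho, -1)
  x <- 1:5; y <- c(2, 1, 4, 3, 5)
  # oracle: 1 - 6 sum(d^2) / (n (n^2 - 1)) for untied ranks
  d <- rank(x) - rank(y)
  oracle <- 1 - 6 * sum(d^2) / (5 * 24)
  got <- spearman_cor(x, y)
  expect_equal(got$rho, oracle)
  ref <- suppressWarnings(cor.test(x, y, method = "spearman"))
  expect_equal(got$rho, unname(ref$estimate))
  expect_warning(spearman_cor(rep(1, 4), 1:4), "zero rank variance")
})

test_that("chi-square independence matches the direct-formula oracle", {
  # worked demographic example: education counts 33/9 vs 26/12
  tab <- matrix(c(33, 9, 26, 12), 2, byrow = TRUE)
  ct <- chi_square_independence(tab)
  expect_equal(round(ct$statistic, 2), 1.06)
  expect_equal(round(ct$p_value, 2), 0.30)
  # direct Sum (O - E)^2 / E oracle on an arbitrary table
  t2 <- matrix(c(7, 12, 15, 4), 2)
  E <- outer(rowSums(t2), colSums(t2)) / sum(t2)
  expect_equal(chi_square_independence(t2)$statistic,
               sum((t2 - E)^2 / E))
  # proportional table: no association
  t3 <- matrix(c(20, 10, 40, 20), 2, byrow = TRUE)
  expect_equal(chi_square_independence(t3)$statistic, 0)
  expect_equal(chi_square_independence(t3)$p_value, 1)
  # invariance to row and column swaps
  expect_equal(chi_square_independence(tab[2:1, ])$statistic, ct$statistic)
  expect_equal(chi_square_independence(tab[, 2:1])$statistic, ct$statistic)
  expect_error(chi_square_independence(matrix(c(0, 0, 5, 3), 2,
                                              byrow = TRUE)), "margin")
})

test_that("per-frequency comparison flags no frequencies under the null identity", {
  set.seed(44)
  vals <- matrix(runif(31 * 5), 5)
  curves <- lapply(seq_len(5), function(i) curve_from_values(vals[i, ]))
  cmp <- compare_groups_per_frequency(curves, curves)
  expect_length(cmp$significant_freqs, 0)
  expect_true(all(cmp$table$p_bonferroni >= cmp$table$p))
  expect_equal(cmp$table$mean_a, cmp$table$mean_b)
  bad <- lapply(1:5, function(i)
    curve_from_values(runif(7), freqs = seq(30, 60, 5)))
  expect_error(compare_groups_per_frequency(curves, bad), "same frequency")
})

test_that("an injected band-limited group effect is detected as a contiguous band", {
  set.seed(45)
  freqs <- 30:60
  effect <- 1.2 * exp(-(freqs - 40)^2 / (2 * 3^2))   # confined to ~35-45
  gA <- lapply(1:20, function(i) curve_from_values(rnorm(31, 1, 0.25)))
  gB <- lapply(1:20, function(i)
    curve_from_values(rnorm(31, 1, 0.25) + effect))
  cmp <- compare_groups_per_frequency(gA, gB)
  sig <- cmp$significant_freqs
  expect_gt(length(sig), 2)
  expect_true(all(sig >= 33 & sig <= 47))
  expect_equal(sig, seq(min(sig), max(sig)))         # contiguous
  expect_true(all(cmp$table$z[cmp$table$significant] < 0))
})
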