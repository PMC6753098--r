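# Paired samples whose |differences| have distinct ranks, with the negative
# signs placed on chosen ranks so the signed-rank statistic is exact.
pairs_with_statistic <- function(neg_ranks, n = 7) {
  d <- seq_len(n)
  d[neg_ranks] <- -d[neg_ranks]
  list(x = d, y = rep(0, n))
}

test_that("exact signed-rank p-values match enumeration and the base-R oracle", {
  cases <- list(list(neg = integer(0), w = 0),
                list(neg = 2L, w = 2),
                list(neg = c(4L, 5L), w = 9),
                list(neg = c(1L, 3L), w = 4),
                list(neg = 1:7, w = 0))
  for (cs in cases) {
    p <- pairs_with_statistic(cs$neg)
    res <- wilcoxon_exact_paired(p$x, p$y)
    expect_equal(res$statistic, cs$w)
    # oracle 1: explicit enumeration of all 2^7 sign vectors
    expect_equal(res$p_value, oracle_signed_rank_p(cs$w, 7))
    # oracle 2: base R exact distribution
    expect_equal(res$p_value, min(1, 2 * psignrank(cs$w, 7)))
    # oracle 3: base R test
    bw <- wilcox.test(p$x, p$y, paired = TRUE, exact = TRUE)
    expect_equal(res$p_value, bw$p.value)
  }
})

test_that("the n = 7 null distribution has the known cumulative counts", {
  counts <- batlipid:::signed_rank_null_counts(7)
  expect_equal(sum(counts), 2^7)
  expect_equal(counts[1:11], c(1, 1, 1, 2, 2, 3, 4, 5, 5, 6, 7))
  # smallest attainable two-sided exact p at n = 7 is 2/128
  res <- wilcoxon_exact_paired(1:7, rep(0, 7))
  expect_equal(res$p_value, 2 / 128)
})

test_that("ties and zeros are rejected with an approximation escape hatch", {
  expect_error(wilcoxon_exact_paired(c(1, 2, 3, 0, 5, 6, 7), rep(0, 7)),
               "zero")
  expect_error(wilcoxon_exact_paired(c(1, 1, 3, 4, 5, 6, 7), rep(0, 7)),
               "tied")
  res <- wilcoxon_exact_paired(c(1, 1, 3, 4, 5, 6, 7), rep(0, 7),
                               method = "approx")
  expect_false(res$exact)
  expect_lt(res$p_value, 0.05)
  expect_error(wilcoxon_exact_paired(1, 1), "2 pairs")
})

test_that("bootstrap CI is seeded, antisymmetric and degenerate-safe", {
  x <- c(5, 7, 9, 11, 13); y <- c(1, 2, 3, 4, 5)
  a <- bootstrap_ci_mean_diff(x, y, seed = 4)
  b <- bootstrap_ci_mean_diff(x, y, seed = 4)
  expect_identical(a$ci, b$ci)
  # reversal antisymmetry with the same seed
  r <- bootstrap_ci_mean_diff(y, x, seed = 4)
  expect_equal(r$ci, -rev(a$ci))
  expect_equal(r$estimate, -a$estimate)
  # identical pairs: interval collapses onto the constant difference
  cst <- bootstrap_ci_mean_diff(c(3, 4, 5), c(1, 2, 3), seed = 1)
  expect_equal(cst$ci, c(2, 2))
  expect_match(bootstrap_ci_mean_diff(x, y, n_boot = 50, seed = 1)$notes,
               "unreliable")
})

test_that("bootstrap CI covers the true mean difference at nominal-ish rate", {
  set.seed(99)
  cover <- 0
  reps <- 200
  for (i in seq_len(reps)) {
    d <- rnorm(200, 1, 1)
    ci <- bootstrap_ci_mean_diff(d, rep(0, 200), n_boot = 400, seed = i)$ci
    cover <- cover + (ci[1] <= 1 && 1 <= ci[2])
  }
  expect_gte(cover / reps, 0.93)
})

test_that("Spearman rho handles monotone, anti-monotone and permutation-exact cases", {
  x <- 1:10
  expect_equal(spearman_rho(x, x^3)$estimate, 1)
  expect_equal(spearman_rho(x, -2 * x)$estimate, -1)

  # exact permutation p at n = 5 against the 120-permutation brute force
  set.seed(12)
  xs <- rnorm(5); ys <- rnorm(5)
  res <- spearman_rho(xs, ys)
  perms <- batlipid:::all_perms(5)
  rho_of <- function(a, b) cor(rank(a), rank(b))
  rhos <- apply(perms, 1, function(p) rho_of(xs, ys[p]))
  expect_equal(res$p_value, mean(abs(rhos) >= abs(res$estimate) - 1e-12))
  # and against base R's estimate
  expect_equal(res$estimate, unname(cor(xs, ys, method = "spearman")))

  # t-approximation branch cross-checked against base R
  set.seed(31)
  xb <- rnorm(30); yb <- xb + rnorm(30, sd = 2)
  big <- spearman_rho(xb, yb)
  ref <- suppressWarnings(cor.test(xb, yb, method = "spearman"))
  expect_equal(big$estimate, unname(ref$estimate))
  expect_equal(big$p_value, ref$p.value, tolerance = 0.02)
  expect_error(spearman_rho(rep(1, 5), 1:5), "constant")
  expect_error(spearman_rho(1:2, 1:2), "3 observations")
})

test_that("paired power analysis returns the minimal n and is monotone", {
  expect_equal(paired_sample_size(1.45, 0.05, 0.85), 7)
  expect_equal(paired_sample_size(100, 0.05, 0.85), 2)
  # monotonicity: nonincreasing in d and alpha, nondecreasing in power
  expect_gte(paired_sample_size(1.0, 0.05, 0.85), 7)
  expect_lte(paired_sample_size(2.0, 0.05, 0.85), 7)
  expect_gte(paired_sample_size(1.45, 0.01, 0.85),
             paired_sample_size(1.45, 0.05, 0.85))
  expect_gte(paired_sample_size(1.45, 0.05, 0.95),
             paired_sample_size(1.45, 0.05, 0.85))
  expect_error(paired_sample_size(-1), "positive")
  expect_error(paired_sample_size(1e-4, 0.05, 0.99), "unreachable")
})

test_that("noncentral-t power agrees with Monte-Carlo simulation of the paired t-test", {
  n <- paired_sample_size(1.45, 0.05, 0.85)
  tcrit <- qt(0.975, n - 1)
  pw_analytic <- 1 - pt(tcrit, n - 1, 1.45 * sqrt(n)) +
    pt(-tcrit, n - 1, 1.45 * sqrt(n))
  set.seed(123)
  reps <- 1e5
  d <- matrix(rnorm(reps * n, 1.45, 1), ncol = n)
  tt <- rowMeans(d) / (apply(d, 1, sd) / sqrt(n))
  expect_equal(mean(abs(tt) > tcrit), pw_analytic, tolerance = 0.01)
  expect_gte(pw_analytic, 0.85)
})

test_that("blood volume fraction worked examples hold", {
  expect_equal(required_blood_volume_fraction(95, 81, 0.5), 16.5)
  expect_equal(required_blood_volume_fraction(95, 95, 0.5), 2.5)
  expect_equal(required_blood_volume_fraction(100, 50, 0), 50)
  expect_error(required_blood_volume_fraction(50, 95, 0.5), "negative")
})

test_that("water PRF shifts induce only small, continuous FSF biases", {
  expect_lt(abs(prf_shift_sensitivity(0)), 1e-9)
  expect_lt(abs(prf_shift_sensitivity(-0.01, fsf_true = 50)), 1)
  sweep <- vapply(seq(-0.05, 0.05, by = 0.01), prf_shift_sensitivity, 1)
  expect_lt(max(abs(sweep)), 2)          # no swap anywhere in the range
  expect_lt(max(abs(diff(sweep))), 0.5)  # continuity in the shift
})
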