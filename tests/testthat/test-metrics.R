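test_that("adjusted Rand index matches exhaustive pair-counting on all small partitions", {
  parts <- all_partitions(5L, 3L)
  for (a in parts) for (b in parts[c(1, 7, 15, length(parts))]) {
    expect_equal(adjusted_rand_index(a, b), ari_bruteforce(a, b),
                 tolerance = 1e-12)
  }
  # a worked 4-point case against the brute-force oracle
  a <- c(1L, 1L, 2L, 2L); b <- c(1L, 2L, 2L, 2L)
  expect_equal(adjusted_rand_index(a, b), ari_bruteforce(a, b),
               tolerance = 1e-12)
  # third route: an established library implementation
  withr::with_seed(21, for (i in 1:10) {
    u <- sample(1:4, 25, TRUE); v <- sample(1:3, 25, TRUE)
    expect_equal(adjusted_rand_index(u, v), mclust::adjustedRandIndex(u, v),
                 tolerance = 1e-12)
  })
})

test_that("ARI conventions: self-agreement, relabeling, single-cluster sides", {
  x <- c(1L, 1L, 2L, 2L, 3L, 3L)
  expect_identical(adjusted_rand_index(x, x), 1)
  expect_identical(adjusted_rand_index(x, c(3L, 3L, 1L, 1L, 2L, 2L)), 1)
  expect_identical(adjusted_rand_index(x, rep(1L, 6L)), 0)
  expect_true(is.na(adjusted_rand_index(c(NA, NA), c(1L, 2L))))
  # ARI <= 1 across random partition pairs
  withr::with_seed(42, for (i in 1:20) {
    a <- sample(1:3, 12, TRUE); b <- sample(1:3, 12, TRUE)
    expect_lte(adjusted_rand_index(a, b), 1)
  })
})

test_that("Cramer's V matches the brute-force oracle and is permutation invariant", {
  parts <- all_partitions(6L, 3L)
  idx <- c(5L, 40L, 100L, length(parts))
  for (a in parts[idx]) for (b in parts[idx]) {
    expect_equal(as.numeric(cramers_v(a, b)), cramers_v_bruteforce(a, b),
                 tolerance = 1e-12)
  }
  a <- rep(1:3, times = c(10, 20, 30))
  b <- rep(c(2, 3, 1), times = c(10, 20, 30))
  expect_equal(as.numeric(cramers_v(a, b)), 1)
  perm <- c(3L, 1L, 2L)
  expect_equal(as.numeric(cramers_v(a, perm[b])), as.numeric(cramers_v(a, b)))
  expect_identical(as.numeric(cramers_v(a, rep(1L, 60L))), 0)
})

test_that("Cramer's V of independent uniform labels is near its null", {
  withr::with_seed(7, {
    a <- sample(1:3, 10000, TRUE)
    b <- sample(1:3, 10000, TRUE)
    nulls <- replicate(100, as.numeric(cramers_v(sample(a), b)))
  })
  # V is nonnegative; under independence it concentrates near its null mean
  expect_lt(as.numeric(cramers_v(a, b)), mean(nulls) + 3 * stats::sd(nulls))
})

test_that("Davies-Bouldin matches a hand-coded oracle and its edge cases", {
  # three clusters on a line with hand-set coordinates
  pts <- rbind(c(0, 0), c(1, 0), c(5, 0), c(6, 0), c(20, 0), c(22, 0))
  lab <- c(1, 1, 2, 2, 3, 3)
  expect_equal(davies_bouldin(pts, lab), dbi_oracle(pts, lab), tolerance = 1e-12)
  # two singleton clusters at distinct points -> 0
  expect_equal(davies_bouldin(rbind(c(0, 0), c(3, 4)), c(1, 2)), 0)
  # shrinking within-cluster spread at fixed centroids cannot increase DBI
  shrink <- pts
  for (l in unique(lab)) {
    cm <- matrix(colMeans(pts[lab == l, , drop = FALSE]),
                 sum(lab == l), 2, byrow = TRUE)
    shrink[lab == l, ] <- (pts[lab == l, , drop = FALSE] - cm) / 2 + cm
  }
  expect_lte(davies_bouldin(shrink, lab), davies_bouldin(pts, lab))
  expect_true(is.na(davies_bouldin(pts, rep(1, 6))))
  expect_true(is.na(davies_bouldin(rbind(c(0, 0), c(0, 0), c(1, 1), c(1, 1)),
                                   c(1, 2, 1, 2))))
})

test_that("interpretability accuracy finds separable clusters and chance for noise", {
  withr::with_seed(3, {
    x <- cbind(sign = c(stats::rnorm(60, -3), stats::rnorm(60, 3)),
               junk = stats::rnorm(120))
  })
  lab <- rep(1:2, each = 60)
  acc <- interpretability_accuracy(x, lab, list(seed = 5))
  expect_gte(acc, 99)
  # permuted balanced 3-cluster labels ~ chance (33.3%)
  withr::with_seed(9, {
    x3 <- matrix(stats::rnorm(300 * 4), 300)
    lab3 <- sample(rep(1:3, each = 100))
  })
  acc3 <- interpretability_accuracy(x3, lab3, list(seed = 5))
  se <- sqrt(1 / 3 * 2 / 3 / 300) * 100
  expect_lt(abs(acc3 - 100 / 3), 5 * se)
  expect_true(is.na(interpretability_accuracy(x, rep(1, 120))))
  expect_identical(acc, interpretability_accuracy(x, lab, list(seed = 5)))
})

test_that("outcome association is 1 for matching partitions, 0.5 under independence", {
  lab <- rep(1:2, each = 50)
  expect_equal(outcome_association(lab, as.integer(lab == 2)), 1)
  withr::with_seed(11, {
    big_lab <- sample(1:3, 4000, TRUE)
    y <- stats::rbinom(4000, 1, 0.5)
  })
  auc <- outcome_association(big_lab, y)
  expect_lt(abs(auc - 0.5), 0.05)
  # invariant to cluster relabeling
  perm <- c(2L, 3L, 1L)
  expect_equal(outcome_association(perm[big_lab], y), auc, tolerance = 1e-12)
  expect_true(is.na(outcome_association(lab, rep(1L, 100))))
})

test_that("concordance matrix is symmetric with unit diagonal and NA rows for failures", {
  withr::with_seed(13, {
    a <- sample(1:3, 200, TRUE); b <- sample(1:2, 200, TRUE)
  })
  m <- concordance_matrix(list(A = a, B = b, C = a,
                               failed = rep(NA_integer_, 200)))
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)[1:3]), rep(1, 3))
  expect_equal(m["A", "C"], 1)
  expect_true(all(is.na(m["failed", ])))
  expect_lt(m["A", "B"], 0.2)  # independent labels -> near zero
  expect_error(concordance_matrix(list(a, b[1:100])), "different observation")
})
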