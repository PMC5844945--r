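test_that("Friedman statistic is zero for identical scores and matches the formula", {
  same <- matrix(0.7, nrow = 10, ncol = 3)
  r <- friedman_rank_test(same)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  # one algorithm always best, k = 3, N = 10: hand-computed rank sums
  sc <- cbind(best = rep(0.9, 10), mid = rep(0.7, 10), worst = rep(0.5, 10))
  r2 <- friedman_rank_test(sc)
  rbar <- c(1, 2, 3)
  expected <- 12 * 10 / (3 * 4) * (sum(rbar^2) - 3 * 16 / 4)
  expect_equal(r2$statistic, expected)
  expect_equal(unname(r2$avg_ranks), rbar)
})

test_that("Friedman test agrees with stats::friedman.test without ties", {
  set.seed(71)
  sc <- matrix(rnorm(7 * 20), nrow = 20, ncol = 7)
  r <- friedman_rank_test(sc)
  ref <- friedman.test(sc)
  expect_equal(r$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(r$p_value, ref$p.value, tolerance = 1e-12)
})

test_that("Friedman statistic is invariant to label permutation and monotone transforms", {
  set.seed(72)
  sc <- matrix(runif(5 * 12), nrow = 12)
  r1 <- friedman_rank_test(sc)
  r2 <- friedman_rank_test(sc[, c(3, 1, 5, 2, 4)])
  expect_equal(r1$statistic, r2$statistic)
  r3 <- friedman_rank_test(exp(3 * sc))  # monotone within each context row
  expect_equal(r1$statistic, r3$statistic)
})

test_that("Friedman type-I error is controlled under the null", {
  set.seed(73)
  rejects <- 0
  for (rep in 1:500) {
    sc <- matrix(rnorm(70 * 7), nrow = 70, ncol = 7)
    rejects <- rejects + (friedman_rank_test(sc)$p_value <= 0.05)
  }
  expect_lte(rejects / 500, 0.07)
})

test_that("Nemenyi critical difference follows the studentized-range quantile", {
  expect_equal(nemenyi_cd(7, 210),
               qtukey(0.95, 7, Inf) / sqrt(2) * sqrt(7 * 8 / (6 * 210)),
               tolerance = 1e-12)
  # k = 2 reduces to the two-sample normal case: q_{2,Inf}/sqrt(2) = z_{a/2}*sqrt(2)/sqrt(2)
  expect_equal(qtukey(0.95, 2, Inf) / sqrt(2), qnorm(0.975),
               tolerance = 1e-6)
  expect_gt(nemenyi_cd(7, 50), nemenyi_cd(7, 100))  # CD shrinks with N
  expect_error(nemenyi_cd(25, 10), "2..20")
})

test_that("Holm-Bonferroni matches a literal step scan and brackets its neighbors", {
  p <- c(0.001, 0.004, 0.009, 0.02, 0.2, 0.8)
  flags <- holm_bonferroni(p, 0.05)
  # brute force
  m <- length(p); ord <- order(p); expected <- logical(m)
  for (i in seq_len(m)) {
    if (p[ord[i]] <= 0.05 / (m - i + 1)) expected[ord[i]] <- TRUE else break
  }
  expect_equal(flags, expected)
  expect_equal(flags, unname(p.adjust(p, "holm") <= 0.05))
  set.seed(74)
  for (rep in 1:20) {
    pv <- runif(8)^1.5
    h <- holm_bonferroni(pv, 0.05)
    expect_true(all(h[pv <= 0.05 / 8]))       # superset of Bonferroni
    expect_true(all(pv[h] <= 0.05))           # subset of unadjusted
  }
  expect_equal(holm_bonferroni(0.04, 0.05), TRUE)  # m = 1: plain alpha
  expect_false(any(holm_bonferroni(c(0.2, 0.6), 0.05)))
})

test_that("win proportions tally exhaustively and are complementary", {
  sc <- cbind(A = c(0.9, 0.8, 0.7), B = c(0.5, 0.8, 0.6), C = c(0.4, 0.3, 0.9))
  M <- win_proportion_matrix(sc)
  expect_equal(M["A", "B"], (1 + 0.5 + 1) / 3)
  expect_equal(M["A", "C"], 2 / 3)
  expect_equal(M["B", "C"], 2 / 3)
  expect_equal(M + t(M), matrix(1, 3, 3, dimnames = dimnames(M)))
  dominant <- cbind(A = c(1, 1), B = c(0.1, 0.2), C = c(0.3, 0.1))
  Md <- win_proportion_matrix(dominant)
  expect_equal(unname(Md["A", c("B", "C")]), c(1, 1))
  expect_warning(win_proportion_matrix(rbind(sc, c(NA, 1, 2))), "dropped")
})

test_that("family comparison applies one Holm correction across families", {
  set.seed(75)
  null_fam <- matrix(rnorm(15 * 4), 15)
  strong <- matrix(rnorm(15 * 4), 15)
  strong[, 1] <- strong[, 1] + 3
  colnames(null_fam) <- colnames(strong) <- paste0("alg", 1:4)
  cmp <- compare_algorithms(list(null = null_fam, signal = strong))
  expect_true(cmp$summary$rejected[cmp$summary$family == "signal"])
  expect_false(cmp$summary$rejected[cmp$summary$family == "null"])
  expect_true(all(cmp$summary$cd > 0))
})
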