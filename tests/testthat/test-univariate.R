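test_that("MWU AUC separates and complements correctly", {
  r <- mwu_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(r$auc, 1)
  expect_equal(r$U, 4)
  expect_equal(mwu_auc(c(1, 2, 3, 4), c(1, 1, 0, 0))$auc, 0)
  expect_error(mwu_auc(1:4, c(1, 1, 1, 1)), "classes")
})

test_that("MWU AUC with ties equals the brute-force pairwise oracle", {
  set.seed(13)
  for (rep in 1:10) {
    v <- sample(1:4, 8, replace = TRUE)
    l <- c(0, 0, 0, 1, 1, 1, sample(0:1, 2, replace = TRUE))
    if (length(unique(l)) < 2) next
    r <- mwu_auc(v, l)
    expect_equal(r$auc, pairwise_auc_oracle(v, l), tolerance = 1e-12)
    expect_equal(r$auc, r$U / (r$n_neg * r$n_pos))
  }
})

test_that("AUCs of a feature and its negation sum to one", {
  set.seed(14)
  v <- rnorm(30); l <- rbinom(30, 1, 0.4)
  expect_equal(mwu_auc(v, l)$auc + mwu_auc(-v, l)$auc, 1)
})

test_that("MWU p-values track the exact test", {
  set.seed(15)
  for (rep in 1:5) {
    v <- rnorm(40); l <- rbinom(40, 1, 0.5)
    if (length(unique(l)) < 2) next
    p_pkg <- dosiomics:::mwu_pvalue(v, l)
    p_ref <- wilcox.test(v[l == 1], v[l == 0], exact = FALSE,
                         correct = TRUE)$p.value
    expect_equal(p_pkg, p_ref, tolerance = 1e-9)
  }
})

test_that("BCa interval handles degenerate and symmetric cases", {
  expect_warning(ci <- bca_interval(rep(5, 20), function(d, i) mean(d[i]),
                                    B = 50), "degenerate")
  expect_equal(ci, c(5, 5))
})

test_that("BCa interval agrees with the boot package on a mean", {
  set.seed(16)
  x <- rexp(40)
  set.seed(17)
  ci <- bca_interval(x, function(d, i) mean(d[i]), B = 4000)
  b <- boot::boot(x, function(d, i) mean(d[i]), R = 4000)
  ci_ref <- boot::boot.ci(b, type = "bca")$bca[4:5]
  expect_equal(ci[1], ci_ref[1], tolerance = 0.05)
  expect_equal(ci[2], ci_ref[2], tolerance = 0.05)
})

test_that("BCa interval covers a normal mean at roughly nominal rate", {
  set.seed(18)
  hits <- 0
  n_sim <- 120
  for (s in 1:n_sim) {
    x <- rnorm(50)
    ci <- bca_interval(x, function(d, i) mean(d[i]), B = 300)
    if (ci[1] <= 0 && 0 <= ci[2]) hits <- hits + 1
  }
  expect_gte(hits / n_sim, 0.90)
  expect_lte(hits / n_sim, 0.99)
})

test_that("FDR step-down matches a literal transcription of its constants", {
  expect_true(all(gbs_stepdown(rep(0, 5))))
  expect_false(any(gbs_stepdown(rep(1, 5))))
  p <- c(0.001, 0.008, 0.02, 0.2, 0.9)
  m <- 5; q <- 0.05
  crit <- sapply(1:m, function(i) i * q / (m + 1 - i * (1 - q)))
  ok <- sort(p) <= crit
  k <- if (all(ok)) m else which.min(ok) - 1
  expected <- rank(p) <= k
  expect_equal(gbs_stepdown(p, q), expected)
})

test_that("FDR step-down rejects a superset of Bonferroni", {
  set.seed(19)
  for (rep in 1:20) {
    p <- runif(12)^2
    g <- gbs_stepdown(p, 0.05)
    bonf <- p <= 0.05 / length(p)
    expect_true(all(g[bonf]))
  }
})

test_that("step-down FDR is controlled under the global null", {
  # 200 features, n = 150, 200 replicate null cohorts
  set.seed(20)
  n <- 150; m <- 200; reps <- 200
  false_disc <- numeric(reps)
  for (r in seq_len(reps)) {
    l <- rbinom(n, 1, 0.35)
    while (length(unique(l)) < 2) l <- rbinom(n, 1, 0.35)
    X <- matrix(rnorm(n * m), n, m)
    p <- apply(X, 2, function(v) dosiomics:::mwu_pvalue(v, l))
    false_disc[r] <- any(gbs_stepdown(p, 0.05))
  }
  # observed FDR = E[V / max(R, 1)] <= P(any rejection) under the global null
  expect_lte(mean(false_disc), 0.07)
})

test_that("tolerance values invert the logistic model", {
  set.seed(21)
  x <- rnorm(200, 50, 15)
  b0 <- -3; b1 <- 0.1
  y <- rbinom(200, 1, plogis(b0 + b1 * x))
  tv <- tolerance_values(x, y)
  fit <- glm(y ~ x, family = binomial())
  expect_equal(unname(tv["TV20"]),
               unname((qlogis(0.2) - coef(fit)[1]) / coef(fit)[2]),
               tolerance = 1e-9)
  # inverse consistency: predicted probability at TV10 is 0.10
  p_at_tv10 <- plogis(coef(fit)[1] + coef(fit)[2] * tv["TV10"])
  expect_equal(unname(p_at_tv10), 0.10, tolerance = 1e-9)
  # harmful feature: a higher complication probability needs a higher value
  expect_true(tv["TV20"] > tv["TV10"] && tv["TV10"] > tv["TV5"])
})

test_that("protective features reverse the tolerance-value ordering", {
  set.seed(22)
  x <- rnorm(200, 50, 15)
  y <- rbinom(200, 1, plogis(2 - 0.08 * x))
  tv <- tolerance_values(x, y)
  expect_true(tv["TV5"] > tv["TV10"] && tv["TV10"] > tv["TV20"])
})

test_that("non-informative features yield an explicit tolerance error", {
  y <- rep(c(0, 1), 50)
  expect_error(tolerance_values(rep(1, 100), y), "non-informative|slope")
})

test_that("FDR truth bounds follow the independent-error model", {
  b <- fdr_truth_bounds(3, 0.05)
  expect_equal(unname(b["all_true"]), 0.95^3)
  expect_equal(unname(b["at_most_one_false"]), 0.95^3 + 3 * 0.05 * 0.95^2)
  expect_equal(unname(fdr_truth_bounds(5, 0)), c(1, 1))
  b1 <- fdr_truth_bounds(1, 0.05)
  expect_equal(unname(b1), c(0.95, 1))
})

test_that("the screen ranks a strongly predictive feature on top", {
  pl <- planted_volume_table(n = 150, beta = 2)
  scr <- univariate_screen(pl$table, pl$labels, B = 200)
  expect_equal(scr$feature[which.max(scr$auc)], "volume_i")
  expect_true(all(scr$ci_lo <= scr$auc & scr$auc <= scr$ci_hi))
})

test_that("the screen skips constant features with a warning", {
  pl <- planted_volume_table(n = 60)
  tab <- pl$table
  tab$stuck <- 1
  expect_warning(scr <- univariate_screen(tab, pl$labels, B = 100),
                 "constant feature")
  expect_false("stuck" %in% scr$feature)
})

test_that("label permutation rarely yields significant features", {
  set.seed(24)
  hits <- 0
  pl <- planted_volume_table(n = 120, beta = 2)
  for (r in 1:20) {
    perm <- sample(pl$labels)
    p <- apply(as.matrix(pl$table), 2,
               function(v) dosiomics:::mwu_pvalue(v, perm))
    hits <- hits + any(gbs_stepdown(p, 0.05))
  }
  expect_lte(hits / 20, 0.05 + 2 * sqrt(0.05 * 0.95 / 20))
})
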