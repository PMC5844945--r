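test_that("kendall tau matches the O(n^2) pair-count oracle", {
  expect_equal(kendall_tau(1:3, 1:3), 1)
  expect_equal(kendall_tau(1:3, 3:1), -1)
  set.seed(5)
  for (rep in 1:10) {
    x <- sample(1:4, 6, replace = TRUE)  # ties likely
    y <- rnorm(6)
    if (sd(x) == 0) next
    expect_equal(kendall_tau(x, y), kendall_oracle(x, y), tolerance = 1e-12)
  }
  expect_error(kendall_tau(rep(1, 5), 1:5), "constant")
})

test_that("kendall tau is antisymmetric under order reversal of one argument", {
  set.seed(6)
  x <- rnorm(8); y <- rnorm(8)
  expect_equal(kendall_tau(x, -y), -kendall_tau(x, y), tolerance = 1e-12)
})

test_that("concordance probability maps tau to pair-agreement probability", {
  expect_equal(concordance_probability(0.5), 0.75)
  expect_equal(concordance_probability(1), 1)
  expect_equal(concordance_probability(0), 0.5)
  expect_error(concordance_probability(1.2), "\\[-1, 1\\]")
})

test_that("identical feature pairs are dropped and logged", {
  set.seed(7)
  v <- rnorm(30)
  tab <- data.frame(volume_i = v, volume_c = rnorm(30),
                    compactness_i = v, compactness_c = rnorm(30))
  # make compactness correlated with volume in BOTH glands
  tab$compactness_c <- tab$volume_c + rnorm(30, sd = 0.1)
  res <- redundancy_filter(tab)
  expect_equal(res$dropped$dropped, "compactness")
  expect_equal(res$dropped$kept, "volume")
  expect_false("compactness_i" %in% names(res$table))
  expect_false("compactness_c" %in% names(res$table))
  expect_true(all(c("volume_i", "volume_c") %in% names(res$table)))
})

test_that("independent features survive the filter", {
  set.seed(8)
  n <- 200
  tab <- data.frame(volume_i = rnorm(n), volume_c = rnorm(n),
                    mean_i = rnorm(n), mean_c = rnorm(n),
                    entropy_i = rnorm(n), entropy_c = rnorm(n))
  res <- redundancy_filter(tab)
  expect_equal(nrow(res$dropped), 0)
  expect_equal(ncol(res$table), 6)
})

test_that("correlation in one gland only does not trigger a drop", {
  set.seed(9)
  n <- 60
  v <- rnorm(n)
  tab <- data.frame(mean_i = v, mean_c = rnorm(n),
                    D50_i = v + rnorm(n, sd = 0.05), D50_c = rnorm(n))
  res <- redundancy_filter(tab)
  expect_equal(nrow(res$dropped), 0)
})

test_that("mean dose is kept over D50 when redundant in both glands", {
  set.seed(10)
  n <- 60
  vi <- rnorm(n); vc <- rnorm(n)
  tab <- data.frame(mean_i = vi, mean_c = vc,
                    D50_i = vi + rnorm(n, sd = 0.05),
                    D50_c = vc + rnorm(n, sd = 0.05))
  res <- redundancy_filter(tab)
  expect_equal(res$dropped$dropped, "D50")
  expect_equal(res$dropped$kept, "mean")
})

test_that("a feature missing from the priority ranking raises an error", {
  set.seed(11)
  v1 <- rnorm(30); v2 <- rnorm(30)
  tab <- data.frame(mean_i = v1, mean_c = v2,
                    D50_i = v1, D50_c = v2)
  expect_error(redundancy_filter(tab, priority = c("volume")), "priority")
})

test_that("feature annotation covers every extracted feature", {
  p <- toy_patient(mean_left = 18, mean_right = 30)
  f <- extract_patient_features(p$dose, p$left, p$right, age = 60,
                                sex = "female")
  ann <- annotate_features(names(f))
  expect_false(anyNA(ann$group))
  expect_setequal(unique(ann$group), setdiff(feature_group_names(), character(0)))
  expect_equal(sum(ann$side == "patient-level"), 2)
  expect_equal(sum(ann$side == "ipsi"), 60)
  expect_equal(sum(ann$side == "contra"), 60)
})

test_that("extraction is invariant to the original left/right labeling", {
  p <- toy_patient(mean_left = 18, mean_right = 30)
  f1 <- extract_patient_features(p$dose, p$left, p$right, 60, "male")
  # mirror the whole patient and swap gland labels: same physical situation
  f2 <- extract_patient_features(flip_sagittal(p$dose),
                                 flip_sagittal(p$right),
                                 flip_sagittal(p$left), 60, "male")
  expect_equal(f1, f2, tolerance = 1e-9)
})
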