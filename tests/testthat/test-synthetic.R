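test_that("digitized ellipsoid volumes match the analytic formula", {
  g <- dose_grid(array(0, c(60, 50, 60)), 1)
  m <- make_parotid_mask(c(15, 12, 20), c(30, 25, 30), g)
  expect_lt(abs(mask_volume(m) - 4 / 3 * pi * 15 * 12 * 20) /
            (4 / 3 * pi * 15 * 12 * 20), 0.05)
  sphere <- make_parotid_mask(c(12, 12, 12), c(30, 25, 30), g)
  expect_lt(shape_features(sphere)$eccentricity, 0.05)
  expect_error(make_parotid_mask(c(40, 10, 10), c(30, 25, 30), g), "bounds")
})

test_that("mirrored glands have identical volumes", {
  g <- dose_grid(array(0, c(61, 41, 41)), 1)
  left <- make_parotid_mask(c(10, 9, 12), c(45, 20, 20), g)
  right <- make_parotid_mask(c(10, 9, 12), c(15, 20, 20), g)
  expect_equal(mask_volume(left), mask_volume(right))
})

test_that("dose fields hit their target mean and gradient", {
  g <- dose_grid(array(0, c(40, 30, 30)), 2)
  m <- make_parotid_mask(c(12, 10, 14), c(39, 29, 29), g)
  d0 <- make_dose_field(g, 25, c(0, 0, 0), c(39, 29, 29), noise_sd = 0)
  expect_true(all(d0$values == 25))
  expect_equal(mean_dose(d0, m), 25)
  set.seed(81)
  d1 <- make_dose_field(g, 25, c(1.5, 0, 0), c(39, 29, 29), noise_sd = 0.5)
  grad <- dose_gradients(d1, m)
  expect_equal(unname(grad["gradient_x"]), 1.5, tolerance = 0.02)
  expect_equal(unname(grad["gradient_y"]), 0, tolerance = 0.02)
})

test_that("cohorts are byte-identical under a fixed seed", {
  p <- simulation_params(n_patients = 5)
  c1 <- simulate_cohort(p, seed = 9)
  c2 <- simulate_cohort(p, seed = 9)
  expect_identical(c1$followups, c2$followups)
  expect_identical(c1$volumes[[3]]$dose$values, c2$volumes[[3]]$dose$values)
  c3 <- simulate_cohort(p, seed = 10)
  expect_false(identical(c1$followups, c3$followups))
})

test_that("null outcome coefficients give chance-level feature AUCs", {
  p <- simulation_params(n_patients = 120,
                         beta = c(intercept = -0.3, volume_c = 0,
                                  gradient_x_c = 0, sex = 0, time = 0))
  x <- simulate_cohort(p, seed = 11)
  eps <- build_time_specific(as_cohort(x))
  lab <- eps$long_term
  truth <- x$latent[match(lab$id, x$latent$id), ]
  for (col in c("volume_contra", "gradient_x_contra")) {
    auc <- mwu_auc(truth[[col]], lab$label)$auc
    expect_lt(abs(auc - 0.5), 0.1)
  }
})

test_that("achieved prevalence tracks the logistic model", {
  p <- simulation_params(n_patients = 200)
  x <- simulate_cohort(p, seed = 12)
  target <- mean(plogis(x$latent$linear_predictor))
  achieved <- mean(x$followups$grade >= 2)
  se <- sqrt(target * (1 - target) / nrow(x$followups))
  expect_lt(abs(achieved - target), 3 * se + 0.02)
})

test_that("visit schedule has ~3-month spacing within 24 months", {
  x <- simulate_cohort(simulation_params(n_patients = 40), seed = 13)
  expect_true(all(x$followups$time_months <= 24))
  gaps <- unlist(lapply(split(x$followups$time_months, x$followups$id),
                        function(t) diff(sort(t))))
  expect_equal(mean(gaps), 3, tolerance = 0.15)
})

test_that("a planted volume effect is recovered through real extraction", {
  p <- simulation_params(n_patients = 80)
  x <- simulate_cohort(p, seed = 14)
  tab <- cohort_feature_table(x)
  eps <- build_time_specific(as_cohort(x))
  lab <- eps$long_term
  rows <- match(lab$id, tab$patient_id)
  auc_raw <- mwu_auc(tab$volume_c[rows], lab$label)$auc
  # protective effect: low volume, high risk
  expect_gte(1 - auc_raw, 0.70)
  # extracted contra volume agrees with the generating analytic volume
  expect_equal(cor(tab$volume_c, x$latent$volume_contra), 1, tolerance = 0.01)
})

test_that("synthetic cohorts round-trip to disk with a manifest", {
  x <- simulate_cohort(simulation_params(n_patients = 3), seed = 15)
  dir <- file.path(tempdir(), "cohort_rt")
  write_synthetic_cohort(x, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  coh <- read_cohort(file.path(dir, "patients.csv"),
                     file.path(dir, "followups.csv"))
  expect_equal(nrow(coh$patients), 3)
  d <- read_volume(file.path(dir, "P001_dose.nii.gz"), "dose")
  expect_equal(d$values, x$volumes[["P001"]]$dose$values, tolerance = 1e-12)
  m <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(m$seed, 15)
})
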