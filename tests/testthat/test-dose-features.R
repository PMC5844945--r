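ball20 <- ball_mask(r = 10, spacing = 1)

test_that("DVH of a constant dose is degenerate", {
  d <- dose_grid(array(20, dim(ball20$values)), 1)
  f <- dvh_features(d, ball20)
  expect_equal(unname(f["mean"]), 20)
  expect_equal(unname(f["spread"]), 0)
  expect_equal(unname(f["V10"]), 1)
  expect_equal(unname(f["V25"]), 0)
  expect_equal(unname(f["entropy"]), 0)
  expect_equal(unname(f["uniformity"]), 1)
  expect_equal(unname(f["D2"]), unname(f["D50"]))
  expect_equal(unname(f["D98"]), 20)
})

test_that("two-point dose distribution has textbook DVH statistics", {
  vals <- array(0, c(4, 4, 4))
  mask <- organ_mask(array(TRUE, c(4, 4, 4)), 1)
  vals[seq_len(32)] <- 10; vals[33:64] <- 30
  d <- dose_grid(vals, 1)
  f <- dvh_features(d, mask)
  expect_equal(unname(f["mean"]), 20)
  expect_equal(unname(f["V20"]), 0.5)
  expect_equal(unname(f["entropy"]), 1)     # 1 bit
  expect_equal(unname(f["uniformity"]), 0.5)
  expect_equal(unname(f["skewness"]), 0)
})

test_that("DVH D- and V-values are monotone on random fields", {
  set.seed(11)
  for (rep in 1:5) {
    d <- dose_grid(array(runif(prod(dim(ball20$values)), 0, 60),
                         dim(ball20$values)), 1)
    f <- dvh_features(d, ball20)
    dvals <- f[paste0("D", c(2, seq(10, 90, 10), 98))]
    expect_true(all(diff(dvals) <= 1e-12))
    vvals <- f[paste0("V", seq(10, 45, 5))]
    expect_true(all(diff(vvals) <= 1e-12))
    expect_gte(unname(f["spread"]), 0)
    expect_true(f["uniformity"] >= 0 && f["uniformity"] <= 1)
  }
})

test_that("subvolume means of a uniform dose are all equal", {
  d <- dose_grid(array(7, dim(ball20$values)), 1)
  s <- subvolume_mean_doses(d, ball20)
  expect_length(s, 9)
  expect_true(all(abs(s - 7) < 1e-12))
})

test_that("subvolume means order along a ramp and flip correctly", {
  d <- grid_from_fn(function(x, y, z) 10 + 2 * x, dims = dim(ball20$values))
  s <- subvolume_mean_doses(d, ball20)
  expect_true(s["sx1"] < s["sx2"] && s["sx2"] < s["sx3"])
  expect_equal(unname(s["sy1"]), unname(s["sy3"]), tolerance = 1e-9)
  # slab symmetry under the flip is exact when the bounding box divides by 3
  box <- grid_from_fn(function(x, y, z)
    x >= 2 & x <= 22 & y >= 3 & y <= 17 & z >= 3 & z <= 17,
    dims = c(25, 21, 21), type = "mask")
  db <- grid_from_fn(function(x, y, z) 10 + 2 * x, dims = c(25, 21, 21))
  sb <- subvolume_mean_doses(db, box)
  sfb <- subvolume_mean_doses(flip_sagittal(db), flip_sagittal(box))
  expect_equal(unname(sfb["sx1"]), unname(sb["sx3"]), tolerance = 1e-9)
  expect_equal(unname(sfb["sx3"]), unname(sb["sx1"]), tolerance = 1e-9)
  expect_equal(unname(sfb["sy2"]), unname(sb["sy2"]), tolerance = 1e-9)
})

test_that("thin bounding boxes are rejected with the axis named", {
  thin <- grid_from_fn(function(x, y, z) x >= 4 & x < 6 & y > 1 & y < 8 & z > 1 & z < 8,
                       dims = c(10, 10, 10), type = "mask")
  d <- dose_grid(array(1, c(10, 10, 10)), 1)
  expect_error(subvolume_mean_doses(d, thin), "axis x")
})

test_that("gradients recover affine fields exactly and flip sign in x", {
  d <- grid_from_fn(function(x, y, z) 5 + 1.5 * x, dims = dim(ball20$values))
  g <- dose_gradients(d, ball20)
  expect_equal(unname(g), c(1.5, 0, 0), tolerance = 1e-9)
  const <- dose_grid(array(3, dim(ball20$values)), 1)
  expect_equal(unname(dose_gradients(const, ball20)), c(0, 0, 0),
               tolerance = 1e-12)
  gf <- dose_gradients(flip_sagittal(d), flip_sagittal(ball20))
  expect_equal(unname(gf["gradient_x"]), -1.5, tolerance = 1e-9)
})

test_that("planar masks are rejected for the gradient fit", {
  plane <- array(FALSE, c(6, 6, 6)); plane[3, , ] <- TRUE
  d <- dose_grid(array(1, c(6, 6, 6)), 1)
  expect_error(dose_gradients(d, organ_mask(plane, 1)), "planar")
})

test_that("odd moments vanish for mirror-symmetric dose and all are translation invariant", {
  d <- grid_from_fn(function(x, y, z)
    exp(-((x - 10)^2 + (y - 10)^2 + (z - 10)^2) / 50),
    dims = c(21, 21, 21))
  m <- organ_mask(array(TRUE, c(21, 21, 21)), 1)
  eta <- dose_moments(d, m)
  expect_equal(unname(eta["eta300"]), 0, tolerance = 1e-10)
  expect_equal(unname(eta["eta111"]), 0, tolerance = 1e-10)
  # translate the whole volume: origin shift leaves central moments unchanged
  d2 <- dose_grid(d$values, d$spacing, origin = c(10, -7, 3))
  m2 <- organ_mask(m$values, m$spacing, origin = c(10, -7, 3))
  expect_equal(dose_moments(d2, m2), eta, tolerance = 1e-12)
})

test_that("an isotropic Gaussian blob has equal second moments", {
  d <- grid_from_fn(function(x, y, z)
    exp(-((x - 16)^2 + (y - 16)^2 + (z - 16)^2) / (2 * 64)),
    dims = c(33, 33, 33))
  m <- organ_mask(array(TRUE, c(33, 33, 33)), 1)
  eta <- dose_moments(d, m)
  expect_equal(unname(eta["eta200"]), unname(eta["eta020"]), tolerance = 0.02)
  expect_equal(unname(eta["eta200"]), unname(eta["eta002"]), tolerance = 0.02)
})

test_that("moments equal the brute-force summation oracle on a random field", {
  set.seed(21)
  dims <- c(12, 10, 11)
  d <- dose_grid(array(runif(prod(dims), 0, 50), dims), c(1.5, 2, 1),
                 origin = c(3, -2, 5))
  m <- organ_mask(array(runif(prod(dims)) < 0.4, dims), c(1.5, 2, 1),
                  origin = c(3, -2, 5))
  eta <- dose_moments(d, m)
  for (o in list(c(2, 0, 0), c(1, 1, 0), c(3, 0, 0), c(1, 1, 1), c(0, 2, 1))) {
    expect_equal(unname(eta[sprintf("eta%d%d%d", o[1], o[2], o[3])]),
                 moments_oracle(d, m, o[1], o[2], o[3]), tolerance = 1e-10)
  }
})

test_that("odd-p moments flip sign under sagittal flip, others are invariant", {
  set.seed(22)
  dims <- c(14, 12, 12)
  d <- dose_grid(array(runif(prod(dims), 0, 40), dims), 1)
  m <- organ_mask(array(runif(prod(dims)) < 0.5, dims), 1)
  eta <- dose_moments(d, m)
  etaf <- dose_moments(flip_sagittal(d), flip_sagittal(m))
  ord <- rbind(c(2,0,0), c(0,2,0), c(0,0,2), c(1,1,0), c(1,0,1), c(0,1,1),
               c(3,0,0), c(0,3,0), c(0,0,3), c(0,1,2), c(0,2,1), c(1,2,0),
               c(1,0,2), c(2,1,0), c(2,0,1), c(1,1,1))
  for (i in seq_len(nrow(ord))) {
    nm <- sprintf("eta%d%d%d", ord[i, 1], ord[i, 2], ord[i, 3])
    s <- if (ord[i, 1] %% 2 == 1) -1 else 1
    expect_equal(unname(etaf[nm]), s * unname(eta[nm]), tolerance = 1e-10)
  }
})

test_that("morphological covariates follow their defining moments", {
  p <- toy_patient(mean_left = 18, mean_right = 30)
  lat <- lateralize(p$dose, p$left, p$right)
  mf <- morphological_features(lat$dose, lat$ipsi_mask, lat$contra_mask)
  mi <- dose_moments(lat$dose, lat$ipsi_mask)
  mc <- dose_moments(lat$dose, lat$contra_mask)
  expect_equal(unname(mf["eta111_i"]), unname(mi["eta111"]))
  expect_equal(unname(mf["eta002_c"]), unname(mc["eta002"]))
  expect_equal(unname(mf["eta300_c"]), unname(mc["eta300"]))
  expect_equal(unname(mf["eta110i_eta110c"]),
               unname(mi["eta110"] * mc["eta110"]))
})

test_that("zero total dose in the mask is rejected", {
  d <- dose_grid(array(0, c(5, 5, 5)), 1)
  m <- organ_mask(array(TRUE, c(5, 5, 5)), 1)
  expect_error(dose_moments(d, m), "zero")
})
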