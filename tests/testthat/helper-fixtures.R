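# Programmatic fixtures shared across test files.

# Grid filled by a function of physical coordinates (mm).
grid_from_fn <- function(fn, dims = c(20, 20, 20), spacing = c(1, 1, 1),
                         origin = c(0, 0, 0), type = "dose") {
  co <- list(x = origin[1] + (seq_len(dims[1]) - 1) * spacing[1],
             y = origin[2] + (seq_len(dims[2]) - 1) * spacing[2],
             z = origin[3] + (seq_len(dims[3]) - 1) * spacing[3])
  g <- expand.grid(x = co$x, y = co$y, z = co$z)
  vals <- array(fn(g$x, g$y, g$z), dim = dims)
  if (type == "mask") organ_mask(vals, spacing, origin)
  else if (type == "image") image_grid(vals, spacing, origin)
  else dose_grid(vals, spacing, origin)
}

# Digitized ball mask of radius r (mm) centered in a grid.
ball_mask <- function(r = 8, spacing = 1, pad = 3) {
  n <- ceiling(2 * r / spacing) + 2 * pad
  ctr <- (n - 1) * spacing / 2
  grid_from_fn(function(x, y, z) (x - ctr)^2 + (y - ctr)^2 + (z - ctr)^2 <= r^2,
               dims = rep(n, 3), spacing = rep(spacing, 3), type = "mask")
}

# Small two-gland test patient: dose ramp along x, two ellipsoid masks.
toy_patient <- function(mean_left = 20, mean_right = 30, gx = 0.5,
                        noise_sd = 0, seed = 42) {
  set.seed(seed)
  dims <- c(40, 24, 24)
  g <- dose_grid(array(0, dims), c(2, 2, 2))
  ext <- (dims - 1) * 2
  left <- make_parotid_mask(c(9, 9, 10), c(ext[1] * 0.75, ext[2] / 2, ext[3] / 2),
                            g, laterality = "left")
  right <- make_parotid_mask(c(9, 9, 10), c(ext[1] * 0.25, ext[2] / 2, ext[3] / 2),
                             g, laterality = "right")
  co <- seq(0, ext[1], by = 2)
  # linear blend between the two gland means plus a local gradient
  fl <- function(x, y, z) {
    w <- x / ext[1]
    (1 - w) * mean_right + w * mean_left + gx * (y - ext[2] / 2) * 0
  }
  vals <- array(0, dims)
  for (i in seq_len(dims[1]))
    vals[i, , ] <- (1 - co[i] / ext[1]) * mean_right + co[i] / ext[1] * mean_left
  if (noise_sd > 0) vals <- pmax(vals + rnorm(length(vals), 0, noise_sd), 0)
  dose <- dose_grid(vals, c(2, 2, 2))
  list(dose = dose, left = left, right = right)
}

# Brute-force oracles -------------------------------------------------------

# O(n^2) pairwise AUC with 0.5 per tie.
pairwise_auc_oracle <- function(values, labels) {
  pos <- values[labels == 1]; neg <- values[labels == 0]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# O(n^2) Kendall tau-b.
kendall_oracle <- function(x, y) {
  n <- length(x); C <- 0; D <- 0; tx <- 0; ty <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- sign(x[j] - x[i]); b <- sign(y[j] - y[i])
    if (a * b > 0) C <- C + 1 else if (a * b < 0) D <- D + 1
    if (a == 0) tx <- tx + 1
    if (b == 0) ty <- ty + 1
  }
  n0 <- n * (n - 1) / 2
  (C - D) / sqrt((n0 - tx) * (n0 - ty))
}

# Direct double-loop summation of normalized central dose moments.
moments_oracle <- function(dose, mask, p, q, r) {
  idx <- which(mask$values, arr.ind = TRUE)
  sp <- mask$spacing; orig <- mask$origin
  mu0 <- 0; cx <- cy <- cz <- 0
  for (row in seq_len(nrow(idx))) {
    d <- dose$values[idx[row, 1], idx[row, 2], idx[row, 3]]
    mu0 <- mu0 + d
    cx <- cx + d * (orig[1] + (idx[row, 1] - 1) * sp[1])
    cy <- cy + d * (orig[2] + (idx[row, 2] - 1) * sp[2])
    cz <- cz + d * (orig[3] + (idx[row, 3] - 1) * sp[3])
  }
  cx <- cx / mu0; cy <- cy / mu0; cz <- cz / mu0
  mu <- 0
  for (row in seq_len(nrow(idx))) {
    d <- dose$values[idx[row, 1], idx[row, 2], idx[row, 3]]
    mu <- mu + d * (orig[1] + (idx[row, 1] - 1) * sp[1] - cx)^p *
      (orig[2] + (idx[row, 2] - 1) * sp[2] - cy)^q *
      (orig[3] + (idx[row, 3] - 1) * sp[3] - cz)^r
  }
  as.numeric(mu / mu0^(1 + (p + q + r) / 3))
}

# Feature table with a planted signal: outcome depends on "volume" only.
planted_volume_table <- function(n = 150, beta = 2, seed = 7) {
  set.seed(seed)
  vol <- rnorm(n)
  noise <- matrix(rnorm(n * 5), n)
  colnames(noise) <- paste0("noise", 1:5)
  labels <- rbinom(n, 1, plogis(-0.2 - beta * vol))
  list(table = data.frame(volume_i = vol, noise), labels = labels)
}
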