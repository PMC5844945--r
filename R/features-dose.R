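#' Dose-volume histogram features of a gland
#'
#' Summarizes the distribution of dose over the masked voxels: `mean` and
#' `spread` (population SD, Gy), `skewness` (third standardized moment),
#' near-minimum/near-maximum and decile doses `D2, D98, D10..D90` (Gy; `Dx`
#' is the smallest dose received by at least x% of the gland volume, linearly
#' interpolated between order statistics), volume fractions `V10..V45` (unit
#' fraction of gland volume receiving at least x Gy), and histogram `entropy`
#' (bits) and `uniformity` over fixed 1-Gy bins from 0 to the maximum dose.
#'
#' @param dose a [dose_grid()].
#' @param mask an [organ_mask()] with at least 2 voxels, same lattice.
#' @param d_percents,v_thresholds_gy percent volumes for `Dx` and Gy
#'   thresholds for `Vx`.
#' @param bin_width_gy histogram bin width for entropy/uniformity.
#' @return named numeric vector.
#' @export
dvh_features <- function(dose, mask,
                         d_percents = c(2, 98, seq(10, 90, by = 10)),
                         v_thresholds_gy = seq(10, 45, by = 5),
                         bin_width_gy = 1) {
  stopifnot_same_geometry(dose, mask, "dose and mask")
  d <- dose$values[mask$values]
  if (length(d) < 2) stop("mask must contain at least 2 voxels")
  n <- length(d)
  m <- mean(d)
  sd_pop <- sqrt(mean((d - m)^2))
  skew <- if (sd_pop > 0) mean((d - m)^3) / sd_pop^3 else 0
  # Dx: dose exceeded by x% of the volume = (1 - x/100) quantile,
  # linear interpolation between order statistics (type 7).
  dx <- stats::quantile(d, probs = 1 - d_percents / 100, type = 7,
                        names = FALSE)
  names(dx) <- paste0("D", d_percents)
  vx <- vapply(v_thresholds_gy, function(t) mean(d >= t), numeric(1))
  names(vx) <- paste0("V", v_thresholds_gy)
  nbins <- max(ceiling(max(d) / bin_width_gy), 1)
  cnt <- tabulate(pmin(floor(d / bin_width_gy), nbins - 1) + 1L,
                  nbins = nbins)
  p <- cnt[cnt > 0] / n
  c(mean = m, spread = sd_pop, skewness = skew, dx, vx,
    entropy = -sum(p * log2(p)), uniformity = sum(p^2))
}

#' Subvolume mean doses
#'
#' Cuts the mask bounding box along each axis into three equal-width slabs
#' (remainder voxels in the last slab) and returns the mean dose over the
#' mask voxels of each slab, ordered along the positive axis: `sx1..sx3`
#' right-to-left, `sy1..sy3` anterior-to-posterior, `sz1..sz3`
#' inferior-to-superior.
#'
#' @inheritParams dvh_features
#' @return named numeric vector of 9 values (Gy).
#' @export
subvolume_mean_doses <- function(dose, mask) {
  stopifnot_same_geometry(dose, mask, "dose and mask")
  if (!any(mask$values)) stop("mask is empty")
  idx <- which(mask$values, arr.ind = TRUE)
  d <- dose$values[mask$values]
  out <- numeric(0)
  for (ax in 1:3) {
    rng <- range(idx[, ax])
    n_ax <- rng[2] - rng[1] + 1L
    if (n_ax < 3)
      stop("mask bounding box spans fewer than 3 voxels along axis ",
           c("x", "y", "z")[ax])
    w <- n_ax %/% 3L
    rel <- idx[, ax] - rng[1]            # 0-based within bounding box
    slab <- pmin(rel %/% w, 2L)          # remainder joins the last slab
    means <- vapply(0:2, function(s) mean(d[slab == s]), numeric(1))
    names(means) <- paste0("s", c("x", "y", "z")[ax], 1:3)
    out <- c(out, means)
  }
  out
}

#' Spatial dose gradients
#'
#' Least-squares affine fit `D ~ a + gx x + gy y + gz z` over the mask voxel
#' centers (mm); returns the slope coefficients in Gy/mm.
#'
#' @inheritParams dvh_features
#' @return named numeric vector `c(gradient_x, gradient_y, gradient_z)`.
#' @export
dose_gradients <- function(dose, mask) {
  stopifnot_same_geometry(dose, mask, "dose and mask")
  if (!any(mask$values)) stop("mask is empty")
  co <- mask_coords(mask)
  for (ax in 1:3) if (length(unique(co[, ax])) < 2)
    stop("mask is planar along axis ", c("x", "y", "z")[ax],
         ": gradient fit is rank-deficient")
  X <- cbind(1, co)
  fit <- stats::lm.fit(X, dose$values[mask$values])
  if (fit$rank < 4) stop("rank-deficient coordinate matrix in gradient fit")
  g <- fit$coefficients[2:4]
  names(g) <- c("gradient_x", "gradient_y", "gradient_z")
  g
}

moment_orders <- function() {
  rbind(c(2,0,0), c(0,2,0), c(0,0,2), c(1,1,0), c(1,0,1), c(0,1,1),
        c(3,0,0), c(0,3,0), c(0,0,3), c(0,1,2), c(0,2,1), c(1,2,0),
        c(1,0,2), c(2,1,0), c(2,0,1), c(1,1,1))
}

moment_name <- function(p, q, r) sprintf("eta%d%d%d", p, q, r)

#' Normalized central dose moments
#'
#' Treats the dose within the mask as a spatial density: with the
#' dose-weighted centroid `(xbar, ybar, zbar)` over mask voxel centers (mm),
#' the central moment is
#' `mu_pqr = sum_v D(v) (x - xbar)^p (y - ybar)^q (z - zbar)^r`
#' and the scale-normalized moment is
#' `eta_pqr = mu_pqr / mu_000^(1 + (p+q+r)/3)`.
#' All 16 second- and third-order moments are returned: spread
#' (`eta200, eta020, eta002`), correlation (`eta110, eta101, eta011`),
#' skewness (`eta300, eta030, eta003`) and coskewness
#' (`eta012, eta021, eta120, eta102, eta210, eta201, eta111`).
#'
#' @inheritParams dvh_features
#' @return named numeric vector of the 16 `eta_pqr`.
#' @export
dose_moments <- function(dose, mask) {
  stopifnot_same_geometry(dose, mask, "dose and mask")
  if (!any(mask$values)) stop("mask is empty")
  co <- mask_coords(mask)
  d <- dose$values[mask$values]
  mu0 <- sum(d)
  if (mu0 <= 0) stop("total dose within the mask is zero")
  ctr <- colSums(co * d) / mu0
  dx <- co[, 1] - ctr[1]; dy <- co[, 2] - ctr[2]; dz <- co[, 3] - ctr[3]
  ord <- moment_orders()
  eta <- apply(ord, 1, function(o)
    sum(d * dx^o[1] * dy^o[2] * dz^o[3]) / mu0^(1 + sum(o) / 3))
  names(eta) <- apply(ord, 1, function(o) moment_name(o[1], o[2], o[3]))
  eta
}

#' Covariates of the morphological reference NTCP model
#'
#' The four dose-moment covariates of the morphological logistic model:
#' `eta111` of the ipsilateral gland, `eta002` and `eta300` of the
#' contralateral gland, and the product `eta110_i * eta110_c`.
#'
#' @param dose a [dose_grid()] (already lateralized).
#' @param ipsi_mask,contra_mask the lateralized [organ_mask()]s.
#' @return named numeric vector
#'   `c(eta111_i, eta002_c, eta300_c, eta110i_eta110c)`.
#' @export
morphological_features <- function(dose, ipsi_mask, contra_mask) {
  mi <- dose_moments(dose, ipsi_mask)
  mc <- dose_moments(dose, contra_mask)
  c(eta111_i = unname(mi["eta111"]),
    eta002_c = unname(mc["eta002"]),
    eta300_c = unname(mc["eta300"]),
    eta110i_eta110c = unname(mi["eta110"] * mc["eta110"]))
}
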