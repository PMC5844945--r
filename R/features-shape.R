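#' Radiomic shape features of an organ mask
#'
#' Computes the parotid shape descriptors: volume, surface area, sphericity,
#' eccentricity, compactness and the principal-axis variances
#' `lambda1 >= lambda2 >= lambda3`.
#'
#' Definitions: volume `V` is voxel count times voxel volume (mm^3); area `A`
#' (mm^2) is estimated from the coarea formula — the mask indicator is
#' smoothed with a small Gaussian and the gradient magnitude integrated over
#' the volume, which converges to the surface area of the underlying smooth
#' shape; `sphericity = pi^(1/3) (6V)^(2/3) / A` (1 for a ball);
#' `compactness = V / (sqrt(pi) A^(3/2))` (scale-free, maximal for a ball);
#' `lambda1..3` are the eigenvalues (mm^2) of the covariance of the voxel
#' center coordinates; `eccentricity = sqrt(1 - lambda3/lambda1)` (0 for a
#' ball).
#'
#' @param mask a nonempty [organ_mask()] with at least 2 voxels.
#' @param smooth_sigma Gaussian smoothing width (mm) of the area estimator.
#' @return named list of class `"shape_features"`.
#' @export
shape_features <- function(mask, smooth_sigma = 1.5) {
  if (!inherits(mask, "organ_mask")) stop("mask must be an organ_mask")
  n <- sum(mask$values)
  if (n == 0) stop("mask is empty")
  if (n == 1) stop("single-voxel mask: principal-axis variances are undefined")
  V <- n * voxel_volume(mask)
  A <- mask_surface_area(mask, smooth_sigma)
  co <- mask_coords(mask)
  lambda <- sort(eigen(stats::cov(co), symmetric = TRUE,
                       only.values = TRUE)$values, decreasing = TRUE)
  lambda <- pmax(lambda, 0)
  ecc <- if (lambda[1] > 0) sqrt(max(0, 1 - lambda[3] / lambda[1])) else 0
  structure(list(
    volume = V,
    area = A,
    sphericity = pi^(1 / 3) * (6 * V)^(2 / 3) / A,
    eccentricity = ecc,
    compactness = V / (sqrt(pi) * A^(3 / 2)),
    lambda1 = lambda[1], lambda2 = lambda[2], lambda3 = lambda[3]),
    class = "shape_features")
}

#' @export
print.shape_features <- function(x, ...) {
  cat(sprintf(
    "<shape_features> V=%.0f mm^3, A=%.0f mm^2, sphericity=%.3f, eccentricity=%.3f\n",
    x$volume, x$area, x$sphericity, x$eccentricity))
  invisible(x)
}

# Surface area via the coarea formula on the Gaussian-smoothed indicator:
# A ~ integral |grad chi_sigma| dV, central differences, replicate padding.
mask_surface_area <- function(mask, sigma_mm = 1.5) {
  arr <- mask$values + 0
  sp <- mask$spacing
  for (ax in 1:3) {
    sig_vox <- sigma_mm / sp[ax]
    arr <- convolve_axis_gaussian(arr, ax, sig_vox)
  }
  gx <- central_diff(arr, 1, sp[1])
  gy <- central_diff(arr, 2, sp[2])
  gz <- central_diff(arr, 3, sp[3])
  sum(sqrt(gx^2 + gy^2 + gz^2)) * prod(sp)
}

# 1D Gaussian convolution along one axis with replicate boundary padding.
convolve_axis_gaussian <- function(arr, axis, sigma_vox) {
  r <- max(1L, ceiling(3 * sigma_vox))
  k <- stats::dnorm(-r:r, sd = sigma_vox)
  k <- k / sum(k)
  d <- dim(arr)
  perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  ap <- aperm(arr, perm)
  dp <- dim(ap)
  m <- matrix(ap, nrow = dp[1])
  n <- nrow(m)
  mp <- rbind(m[rep(1, r), , drop = FALSE], m, m[rep(n, r), , drop = FALSE])
  sm <- matrix(0, n, ncol(m))
  for (j in seq_along(k)) sm <- sm + k[j] * mp[(j - 1) + seq_len(n), , drop = FALSE]
  aperm(array(sm, dp), order(perm))
}

central_diff <- function(arr, axis, h) {
  d <- dim(arr)
  n <- d[axis]
  hi <- pmin(seq_len(n) + 1L, n)
  lo <- pmax(seq_len(n) - 1L, 1L)
  sl <- function(idx) switch(axis,
    arr[idx, , , drop = FALSE],
    arr[, idx, , drop = FALSE],
    arr[, , idx, drop = FALSE])
  (sl(hi) - sl(lo)) / (2 * h)
}
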