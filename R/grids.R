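#' Construct a 3D dose grid
#'
#' A dose grid is a 3D scalar field of absorbed dose (Gy) on a regular voxel
#' lattice. Axes follow the LPS convention: the first array dimension runs
#' right-to-left (x), the second anterior-to-posterior (y), the third
#' inferior-to-superior (z). Voxel indices are 0-based in physical-coordinate
#' formulas: the center of voxel `(i, j, k)` (0-based) lies at
#' `origin + c(i, j, k) * spacing` (mm).
#'
#' @param values 3D numeric array of dose per voxel (Gy); finite, non-negative.
#' @param spacing numeric length-3, per-axis voxel size in mm; all positive.
#' @param origin numeric length-3, position of the first voxel center in mm.
#' @return An object of class `c("dose_grid", "volume_grid")`.
#' @seealso [organ_mask()], [resample_to_isotropic()], [lateralize()]
#' @export
dose_grid <- function(values, spacing, origin = c(0, 0, 0)) {
  g <- new_volume_grid(values, spacing, origin, "dose_grid")
  if (any(!is.finite(g$values))) stop("dose values must be finite")
  if (any(g$values < 0)) stop("dose values must be non-negative (Gy)")
  g
}

#' Construct a 3D image grid (e.g. CT)
#'
#' Identical geometry to [dose_grid()] but values are unconstrained image
#' intensities (e.g. Hounsfield units, which may be negative).
#'
#' @inheritParams dose_grid
#' @return An object of class `c("image_grid", "volume_grid")`.
#' @export
image_grid <- function(values, spacing, origin = c(0, 0, 0)) {
  g <- new_volume_grid(values, spacing, origin, "image_grid")
  if (any(!is.finite(g$values))) stop("image values must be finite")
  g
}

#' Construct a binary organ mask
#'
#' A mask marks the voxels belonging to one organ (here, a parotid gland) on
#' the same lattice as its paired dose/image grid.
#'
#' @param values 3D logical (or 0/1 numeric) array.
#' @param spacing,origin as in [dose_grid()].
#' @param laterality `"left"`, `"right"`, or `"unassigned"`.
#' @param role `"ipsi"`, `"contra"`, or `"unassigned"`; assigned by
#'   [lateralize()].
#' @return An object of class `c("organ_mask", "volume_grid")`.
#' @export
organ_mask <- function(values, spacing, origin = c(0, 0, 0),
                       laterality = "unassigned", role = "unassigned") {
  if (is.numeric(values)) values <- array(values != 0, dim = dim(values))
  g <- new_volume_grid(values, spacing, origin, "organ_mask")
  if (!is.logical(g$values)) stop("mask values must be logical")
  g$laterality <- match.arg(laterality, c("left", "right", "unassigned"))
  g$role <- match.arg(role, c("ipsi", "contra", "unassigned"))
  g
}

new_volume_grid <- function(values, spacing, origin, class) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop(class, ": values must be a 3D array")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive finite values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be 3 finite values (mm)")
  structure(list(values = values, spacing = spacing, origin = origin),
            class = c(class, "volume_grid"))
}

#' @export
print.volume_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<%s> %d x %d x %d voxels, spacing (%g, %g, %g) mm\n",
              class(x)[1], d[1], d[2], d[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  if (inherits(x, "organ_mask")) {
    cat(sprintf("  %d voxels set (%.0f mm^3), laterality=%s, role=%s\n",
                sum(x$values), mask_volume(x), x$laterality, x$role))
  } else {
    cat(sprintf("  value range [%g, %g]\n", min(x$values), max(x$values)))
  }
  invisible(x)
}

#' Voxel-center coordinates along each axis (mm)
#' @param grid a volume grid.
#' @return list with numeric vectors `x`, `y`, `z`.
#' @keywords internal
axis_coords <- function(grid) {
  d <- dim(grid$values)
  list(x = grid$origin[1] + (seq_len(d[1]) - 1) * grid$spacing[1],
       y = grid$origin[2] + (seq_len(d[2]) - 1) * grid$spacing[2],
       z = grid$origin[3] + (seq_len(d[3]) - 1) * grid$spacing[3])
}

voxel_volume <- function(grid) prod(grid$spacing)

#' Total mask volume in mm^3
#' @param mask an [organ_mask()].
#' @export
mask_volume <- function(mask) sum(mask$values) * voxel_volume(mask)

#' Voxel-center coordinates (mm) of all set voxels, as an n x 3 matrix
#' @keywords internal
mask_coords <- function(mask) {
  idx <- which(mask$values, arr.ind = TRUE)
  sweep(sweep(idx - 1, 2, mask$spacing, "*"), 2, mask$origin, "+")
}

same_geometry <- function(a, b, tol = 1e-6) {
  identical(dim(a$values), dim(b$values)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

stopifnot_same_geometry <- function(a, b, what = "volumes") {
  if (!same_geometry(a, b))
    stop("geometry mismatch between ", what,
         " (dimensions, spacing and origin must agree)")
  invisible(TRUE)
}

#' Mean dose within a mask
#'
#' @param dose a [dose_grid()].
#' @param mask an [organ_mask()] on the same lattice.
#' @return mean dose in Gy over the masked voxels.
#' @export
mean_dose <- function(dose, mask) {
  stopifnot_same_geometry(dose, mask, "dose and mask")
  if (!any(mask$values)) stop("mask is empty")
  mean(dose$values[mask$values])
}

#' Flip a volume through the sagittal plane
#'
#' Reverses voxel order along the x (right-left) axis. Spacing and origin are
#' unchanged: the flip relabels the lattice in place, so x-odd quantities
#' (gradients, odd-order moments) change sign while volumes and mean doses are
#' preserved.
#'
#' @param grid a volume grid or mask.
#' @return the flipped object, same class.
#' @export
flip_sagittal <- function(grid) {
  d <- dim(grid$values)
  grid$values <- grid$values[d[1]:1, , , drop = FALSE]
  grid
}

# Vectorized trilinear interpolation of a 3D array at physical points (mm).
# Points outside the lattice are clamped to the boundary (used only for the
# sub-voxel overhang the resampler can produce at the far edge).
interp_trilinear <- function(values, spacing, origin, px, py, pz) {
  d <- dim(values)
  fx <- pmin(pmax((px - origin[1]) / spacing[1], 0), d[1] - 1)
  fy <- pmin(pmax((py - origin[2]) / spacing[2], 0), d[2] - 1)
  fz <- pmin(pmax((pz - origin[3]) / spacing[3], 0), d[3] - 1)
  i0 <- pmin(floor(fx), d[1] - 2); i0[d[1] == 1] <- 0
  j0 <- pmin(floor(fy), d[2] - 2); j0[d[2] == 1] <- 0
  k0 <- pmin(floor(fz), d[3] - 2); k0[d[3] == 1] <- 0
  tx <- fx - i0; ty <- fy - j0; tz <- fz - k0
  at <- function(i, j, k) values[1 + i + d[1] * (j + d[2] * k)]
  i1 <- pmin(i0 + 1, d[1] - 1)
  j1 <- pmin(j0 + 1, d[2] - 1)
  k1 <- pmin(k0 + 1, d[3] - 1)
  (1 - tz) * ((1 - ty) * ((1 - tx) * at(i0, j0, k0) + tx * at(i1, j0, k0)) +
              ty       * ((1 - tx) * at(i0, j1, k0) + tx * at(i1, j1, k0))) +
  tz       * ((1 - ty) * ((1 - tx) * at(i0, j0, k1) + tx * at(i1, j0, k1)) +
              ty       * ((1 - tx) * at(i0, j1, k1) + tx * at(i1, j1, k1)))
}

#' Resample a grid or mask to isotropic resolution
#'
#' Dose and image grids are linearly (trilinearly) interpolated onto an
#' isotropic lattice; masks are interpolated the same way and re-binarized at
#' 0.5 so the result stays binary. The physical extent of the volume is
#' preserved to within one voxel: the new lattice starts at the same origin
#' and covers the same span.
#'
#' @param grid a [dose_grid()], [image_grid()] or [organ_mask()].
#' @param target isotropic voxel size in mm (default 1).
#' @return the resampled object, same class and metadata.
#' @export
resample_to_isotropic <- function(grid, target = 1) {
  if (!inherits(grid, "volume_grid")) stop("grid must be a volume grid")
  if (!is.numeric(target) || length(target) != 1L || !is.finite(target) ||
      target <= 0)
    stop("target spacing must be a single positive number (mm)")
  d <- dim(grid$values)
  ax <- c("x", "y", "z")[d < 2]
  if (length(ax))
    stop("cannot resample along degenerate (single-slice) axis ",
         paste(ax, collapse = ", "))
  extent <- (d - 1) * grid$spacing
  nnew <- pmax(floor(extent / target + 1e-9), 1) + 1
  co <- lapply(1:3, function(a)
    grid$origin[a] + (seq_len(nnew[a]) - 1) * target)
  pts <- expand.grid(x = co[[1]], y = co[[2]], z = co[[3]],
                     KEEP.OUT.ATTRS = FALSE)
  is_mask <- inherits(grid, "organ_mask")
  vals <- interp_trilinear(grid$values + 0, grid$spacing, grid$origin,
                           pts$x, pts$y, pts$z)
  arr <- array(vals, dim = nnew)
  out <- grid
  out$spacing <- rep(target, 3)
  out$values <- if (is_mask) arr >= 0.5 else arr
  out
}
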