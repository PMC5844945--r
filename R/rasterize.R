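#' Rasterize a stack of planar contours into an organ mask
#'
#' Structure sets delineate an organ as closed planar polygons, one or more
#' per axial slice, with vertices in mm. A voxel is set iff its center lies
#' inside the polygon(s) of its slice under the even-odd rule; multiple
#' polygons on one slice toggle, so holes are supported.
#'
#' @param contours list of contours; each a list with `vertices` (n x 2 matrix
#'   of (x, y) mm, n >= 3, closed implicitly — a repeated last vertex is
#'   dropped) and `z` (slice position in mm). An empty list yields an empty
#'   mask.
#' @param geometry a [dose_grid()], [image_grid()] or [organ_mask()] supplying
#'   the target lattice.
#' @param laterality passed to [organ_mask()].
#' @return an [organ_mask()] on the target lattice.
#' @export
rasterize_mask <- function(contours, geometry, laterality = "unassigned") {
  if (!inherits(geometry, "volume_grid")) stop("geometry must be a volume grid")
  d <- dim(geometry$values)
  co <- axis_coords(geometry)
  vals <- array(FALSE, dim = d)
  for (ci in seq_along(contours)) {
    cnt <- contours[[ci]]
    v <- as.matrix(cnt$vertices)
    if (nrow(v) >= 2 && all(v[1, ] == v[nrow(v), ])) v <- v[-nrow(v), , drop = FALSE]
    if (nrow(v) < 3)
      stop("open or degenerate polygon in contour ", ci,
           " (slice z=", cnt$z, " mm)")
    if (polygon_self_intersects(v))
      stop("self-intersecting polygon in contour ", ci,
           " (slice z=", cnt$z, " mm)")
    k <- which.min(abs(co$z - cnt$z))
    if (abs(co$z[k] - cnt$z) > geometry$spacing[3] / 2 + 1e-9)
      stop("contour ", ci, " slice position z=", cnt$z,
           " mm lies outside the grid extent")
    inside <- points_in_polygon(rep(co$x, times = d[2]),
                                rep(co$y, each = d[1]), v)
    vals[, , k] <- xor(vals[, , k], matrix(inside, d[1], d[2]))
  }
  organ_mask(vals, geometry$spacing, geometry$origin, laterality = laterality)
}

# Even-odd (crossing number) point-in-polygon test, vectorized over points.
points_in_polygon <- function(px, py, vertices) {
  n <- nrow(vertices)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- vertices[i, 1]; yi <- vertices[i, 2]
    xj <- vertices[j, 1]; yj <- vertices[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# TRUE if any two non-adjacent edges of the closed polygon properly intersect.
polygon_self_intersects <- function(v) {
  n <- nrow(v)
  seg <- cbind(v, v[c(2:n, 1), , drop = FALSE])
  for (i in seq_len(n - 2)) {
    jmax <- if (i == 1) n - 1 else n
    for (j in (i + 2):jmax) {
      if (segments_properly_intersect(seg[i, 1:2], seg[i, 3:4],
                                      seg[j, 1:2], seg[j, 3:4]))
        return(TRUE)
    }
  }
  FALSE
}

segments_properly_intersect <- function(p1, p2, p3, p4) {
  d1 <- cross2(p4 - p3, p1 - p3)
  d2 <- cross2(p4 - p3, p2 - p3)
  d3 <- cross2(p2 - p1, p3 - p1)
  d4 <- cross2(p2 - p1, p4 - p1)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

cross2 <- function(a, b) a[1] * b[2] - a[2] * b[1]
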