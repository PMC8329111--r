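#' Surface Dice similarity coefficient at a distance tolerance
#'
#' The Dice coefficient computed on the two masks' surfaces instead of their
#' volumes: surface elements of A whose nearest distance to surface B is at
#' most `tol` mm (and vice versa) count toward the intersection, so small
#' surface displacements within the tolerance go unpunished. With boundary
#' weights w and directed nearest distances d, the value is
#' (W_A\{d <= tol\} + W_B\{d <= tol\}) / (W_A + W_B).
#'
#' The default `"face-surfel"` boundary gives the metric its surface-area
#' semantics under anisotropic spacing; `"voxel-center"` treats the surface
#' as boundary voxels, in which case at `tol = 0` the value reduces to the
#' weighted fraction of coincident boundary voxels.
#'
#' @param a,b comparable, nonempty [binary_mask] objects.
#' @param tol tolerance in mm, finite and >= 0. Typical evaluation panels
#'   use 0, 4, 8 and 10 mm.
#' @param mode boundary representation, see [extract_boundary_3d].
#' @return value in \[0, 1\]; non-decreasing in `tol`; 1 for identical masks
#'   at any tolerance.
#' @export
surface_dsc <- function(a, b, tol, mode = c("face-surfel", "voxel-center")) {
  mode <- match.arg(mode)
  if (!is.numeric(tol) || length(tol) != 1L || !is.finite(tol) || tol < 0)
    segsim_stop("tolerance must be a single finite value >= 0 (mm)",
                "segsim_parameter_error")
  assert_comparable(a, b)
  sa <- extract_boundary_3d(a, mode)
  sb <- extract_boundary_3d(b, mode)
  dd <- nearest_distances(sa, sb)
  tol_eps <- tol + 1e-9   # guard against FP noise at exact coincidence
  (sum(sa$weights[dd$a_to_b <= tol_eps]) + sum(sb$weights[dd$b_to_a <= tol_eps])) /
    (sum(sa$weights) + sum(sb$weights))
}

#' Percentile Hausdorff distance
#'
#' Pools the directed nearest-surface distances of both directions into one
#' multiset, sorts them ascending, and returns the requested percentile:
#' `p = 100` is the classical (maximum) Hausdorff distance; lower
#' percentiles (99, 98, 95) damp outliers. The percentile uses linear
#' interpolation between closest ranks (quantile type 7), declared so results
#' are reproducible bit-for-bit.
#'
#' @param a,b comparable, nonempty [binary_mask] objects.
#' @param p percentile in (0, 100].
#' @param mode boundary representation; surfaces are read as point sets, so
#'   the default is `"voxel-center"`.
#' @return distance in mm.
#' @export
hausdorff_percentile <- function(a, b, p = 100,
                                 mode = c("voxel-center", "face-surfel")) {
  mode <- match.arg(mode)
  if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p <= 0 || p > 100)
    segsim_stop("percentile must be in (0, 100]", "segsim_parameter_error")
  assert_comparable(a, b)
  dd <- nearest_distances(extract_boundary_3d(a, mode),
                          extract_boundary_3d(b, mode))
  pooled <- c(dd$a_to_b, dd$b_to_a)
  if (p == 100) return(max(pooled))
  unname(quantile(pooled, probs = p / 100, type = 7, names = FALSE))
}

#' Average surface distance
#'
#' The mean nearest distance from surface A to surface B, the mean from B to
#' A, and the average of those two directed means. Note this is not the mean
#' of the pooled distance multiset: when the two surfaces have different
#' element counts the two conventions differ, and the two-directed-means
#' convention is the one implemented.
#'
#' @param a,b comparable, nonempty [binary_mask] objects.
#' @param mode boundary representation, default `"voxel-center"`.
#' @return distance in mm; symmetric in (a, b).
#' @export
average_surface_distance <- function(a, b,
                                     mode = c("voxel-center", "face-surfel")) {
  mode <- match.arg(mode)
  assert_comparable(a, b)
  dd <- nearest_distances(extract_boundary_3d(a, mode),
                          extract_boundary_3d(b, mode))
  (mean(dd$a_to_b) + mean(dd$b_to_a)) / 2
}

# 3D boundary-voxel variant of the edit-path substrate (sensitivity analysis
# only; the slice-wise 2D edge is the default and the reported convention).
boundary3d_voxel_mask <- function(mask) {
  fg <- mask$voxels == 1L
  b <- array(FALSE, dim(fg))
  for (axis in 1:3) for (dir in c(-1L, 1L))
    b <- b | (fg & !neighbor_fg(fg, axis, dir))
  b
}

edge_substrate <- function(mask, mode) {
  if (mode == "slice2d") extract_edges_2d(mask)$edge else boundary3d_voxel_mask(mask)
}

#' Added path length
#'
#' The number of edge pixels of the corrected segmentation that are not edge
#' pixels of the autosegmentation — a proxy for the contour length a human
#' must redraw. Edges are taken per axial slice in 2D (4-connectivity) and
#' membership is exact pixel-index coincidence (a set difference, not a
#' distance criterion); the result is a raw pixel count, never mm. The
#' metric is directional: `a` is the auto mask, `b` the corrected reference.
#'
#' @param a auto mask.
#' @param b corrected mask (comparable with `a`; either may be empty).
#' @param mode `"slice2d"` (default, the reported convention) or
#'   `"boundary3d"` (6-connectivity 3D boundary voxels, for sensitivity
#'   analysis).
#' @return integer pixel count.
#' @export
added_path_length <- function(a, b, mode = c("slice2d", "boundary3d")) {
  mode <- match.arg(mode)
  assert_comparable(a, b)
  ea <- edge_substrate(a, mode)
  eb <- edge_substrate(b, mode)
  as.integer(sum(eb & !ea))
}

#' False negative path length
#'
#' The added path length excluding edge pixels created by shrinking edits:
#' corrected edge pixels that lie inside the auto mask's foreground can only
#' arise from erasing auto voxels, and are excluded. Counts corrected edge
#' pixels that are neither on the auto edge nor inside the auto volume.
#' Always <= the added path length.
#'
#' @inheritParams added_path_length
#' @return integer pixel count.
#' @export
false_negative_path_length <- function(a, b, mode = c("slice2d", "boundary3d")) {
  mode <- match.arg(mode)
  assert_comparable(a, b)
  ea <- edge_substrate(a, mode)
  eb <- edge_substrate(b, mode)
  as.integer(sum(eb & !ea & !(a$voxels == 1L)))
}
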