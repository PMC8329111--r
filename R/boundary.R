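# Shift a logical 3D array by one voxel along an axis, filling the vacated
# plane with FALSE (the lattice border counts as background everywhere).
shift_plane <- function(x, axis, by) {
  d <- dim(x)
  out <- array(FALSE, d)
  n <- d[axis]
  if (n == 1L) return(out)
  src <- dst <- lapply(d, seq_len)
  if (by > 0) { dst[[axis]] <- 2:n; src[[axis]] <- 1:(n - 1) }
  else        { dst[[axis]] <- 1:(n - 1); src[[axis]] <- 2:n }
  out[dst[[1]], dst[[2]], dst[[3]]] <-
    x[src[[1]], src[[2]], src[[3]]]
  out
}

# Face-neighbour presence: neighbour of each voxel in direction `dir` along
# `axis` (out-of-lattice neighbours are background).
neighbor_fg <- function(fg, axis, dir) shift_plane(fg, axis, -dir)

#' Extract the 3D boundary of a mask
#'
#' Boundary voxels are foreground voxels with at least one face-adjacent
#' (6-connectivity) background neighbour; the lattice border counts as
#' background, so structures clipped by the field of view still have a
#' surface there. Two boundary representations are supported:
#'
#' * `"voxel-center"` — one element per boundary voxel; position is the voxel
#'   center in mm and weight the voxel's total exposed face area (mm^2).
#'   Used by default for Hausdorff and average surface distances, where the
#'   surface is read as a set of points.
#' * `"face-surfel"` — one element per exposed voxel face; position is the
#'   face center and weight the face area. Used by default for the surface
#'   Dice coefficient, whose inputs are surface areas.
#'
#' @param mask a [binary_mask] with at least one foreground voxel.
#' @param mode `"voxel-center"` or `"face-surfel"`.
#' @return A `boundary_set`: list with `positions` (n x 3 matrix, mm),
#'   `weights` (mm^2), `mode`, `source_path`.
#' @export
extract_boundary_3d <- function(mask, mode = c("face-surfel", "voxel-center")) {
  mode <- match.arg(mode)
  fg <- mask$voxels == 1L
  if (!any(fg))
    segsim_stop("mask has no foreground voxels: surface is undefined",
                "segsim_empty_surface_error")
  sp <- mask$spacing
  face_area <- c(sp[2] * sp[3], sp[1] * sp[3], sp[1] * sp[2])

  if (mode == "voxel-center") {
    weight <- array(0, dim(fg))
    for (axis in 1:3) for (dir in c(-1L, 1L)) {
      exposed <- fg & !neighbor_fg(fg, axis, dir)
      weight <- weight + exposed * face_area[axis]
    }
    idx <- which(fg & weight > 0, arr.ind = TRUE)
    pos <- sweep(idx - 1, 2, sp, "*")
    w <- weight[fg & weight > 0]
  } else {
    pos_list <- list(); w_list <- list()
    for (axis in 1:3) for (dir in c(-1L, 1L)) {
      exposed <- fg & !neighbor_fg(fg, axis, dir)
      if (!any(exposed)) next
      idx <- which(exposed, arr.ind = TRUE)
      p <- sweep(idx - 1, 2, sp, "*")
      p[, axis] <- p[, axis] + dir * sp[axis] / 2
      pos_list[[length(pos_list) + 1L]] <- p
      w_list[[length(w_list) + 1L]] <- rep(face_area[axis], nrow(idx))
    }
    pos <- do.call(rbind, pos_list)
    w <- unlist(w_list)
  }
  dimnames(pos) <- NULL
  structure(list(positions = pos, weights = as.numeric(w), mode = mode,
                 source_path = mask$source_path),
            class = "boundary_set")
}

#' Extract per-slice 2D edge pixels
#'
#' For each axial slice (third array axis), edge pixels are foreground pixels
#' with at least one 4-connected in-plane background neighbour; the slice
#' border counts as background. Structures one pixel thick are entirely edge.
#' These per-slice edge sets are the substrate for the added path length and
#' false negative path length.
#'
#' @param mask a [binary_mask]; may be empty (empty edge set).
#' @return A `slice_edge_set`: list with `edge` (logical 3D array marking
#'   edge pixels), `per_slice` (integer counts by slice) and `total_count`.
#' @export
extract_edges_2d <- function(mask) {
  fg <- mask$voxels == 1L
  edge <- fg & (!neighbor_fg(fg, 1, 1L) | !neighbor_fg(fg, 1, -1L) |
                !neighbor_fg(fg, 2, 1L) | !neighbor_fg(fg, 2, -1L))
  per_slice <- apply(edge, 3, sum)
  structure(list(edge = edge, per_slice = as.integer(per_slice),
                 total_count = as.integer(sum(edge))),
            class = "slice_edge_set")
}

#' Directed nearest distances between two boundaries
#'
#' For every element of boundary A the Euclidean distance (mm) to its nearest
#' element of B, and vice versa — the ingredients of the Hausdorff family,
#' the average surface distance, and the surface Dice coefficient.
#'
#' @param a,b `boundary_set` objects (nonempty).
#' @return A `directed_distance_set`: list with `a_to_b` and `b_to_a`
#'   numeric vectors (mm), ordered as the elements of `a` and `b`.
#' @export
nearest_distances <- function(a, b) {
  for (s in list(a, b)) {
    if (!inherits(s, "boundary_set"))
      segsim_stop("inputs must be boundary_set objects", "segsim_type_error")
    if (nrow(s$positions) == 0L)
      segsim_stop("empty boundary set: distances are undefined",
                  "segsim_empty_surface_error")
  }
  structure(list(a_to_b = nn_min_distances_cpp(a$positions, b$positions),
                 b_to_a = nn_min_distances_cpp(b$positions, a$positions)),
            class = "directed_distance_set")
}
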