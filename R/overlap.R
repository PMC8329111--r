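#' Voxel overlap counts between two masks
#'
#' @param a,b comparable [binary_mask] objects.
#' @return list with `n_a`, `n_b`, `n_intersect`, `n_union`, `n_b_minus_a`.
#' @export
overlap_counts <- function(a, b) {
  assert_comparable(a, b)
  fa <- a$voxels == 1L; fb <- b$voxels == 1L
  n_a <- sum(fa); n_b <- sum(fb); n_i <- sum(fa & fb)
  list(n_a = n_a, n_b = n_b, n_intersect = n_i,
       n_union = n_a + n_b - n_i, n_b_minus_a = n_b - n_i)
}

#' Volumetric Dice similarity coefficient
#'
#' Twice the voxel overlap of the two masks divided by the sum of their
#' voxel counts: 1 means perfect overlap, 0 no overlap. If both masks are
#' empty the result is 1 by convention (perfect agreement on absence,
#' resolving the 0/0 form); if exactly one is empty it is 0.
#'
#' @param a,b comparable [binary_mask] objects.
#' @return value in \[0, 1\].
#' @export
volumetric_dsc <- function(a, b) {
  oc <- overlap_counts(a, b)
  if (oc$n_a == 0L && oc$n_b == 0L) return(1)
  if (oc$n_a == 0L || oc$n_b == 0L) return(0)
  2 * oc$n_intersect / (oc$n_a + oc$n_b)
}

#' Jaccard index
#'
#' Voxel overlap divided by voxel union. Related to the Dice coefficient by
#' DSC = 2J / (1 + J); the two coincide at 0 and 1. Empty-mask conventions
#' as in [volumetric_dsc].
#'
#' @param a,b comparable [binary_mask] objects.
#' @return value in \[0, 1\].
#' @export
jaccard_index <- function(a, b) {
  oc <- overlap_counts(a, b)
  if (oc$n_a == 0L && oc$n_b == 0L) return(1)
  if (oc$n_a == 0L || oc$n_b == 0L) return(0)
  oc$n_intersect / oc$n_union
}

#' False negative volume
#'
#' The number of voxels in the corrected mask that are absent from the auto
#' mask — the volume a human must add. Directional, and reported as a raw
#' voxel ("pixel") count, not mm^3; multiply by `prod(spacing)` for mm^3.
#'
#' @param a auto mask.
#' @param b corrected mask.
#' @return integer voxel count.
#' @export
false_negative_volume <- function(a, b) {
  oc <- overlap_counts(a, b)
  as.integer(oc$n_b_minus_a)
}
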