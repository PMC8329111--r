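# Oracle surface metrics computed from brute-force boundary sets/distances.
oracle_surface_dsc <- function(a, b, tol) {
  sa <- extract_boundary_3d(a, "face-surfel")
  sb <- extract_boundary_3d(b, "face-surfel")
  dab <- oracle_nn(sa$positions, sb$positions)
  dba <- oracle_nn(sb$positions, sa$positions)
  (sum(sa$weights[dab <= tol]) + sum(sb$weights[dba <= tol])) /
    (sum(sa$weights) + sum(sb$weights))
}

oracle_pooled_distances <- function(a, b) {
  pa <- oracle_boundary_positions(a)
  pb <- oracle_boundary_positions(b)
  c(oracle_nn(pa, pb), oracle_nn(pb, pa))
}

test_that("surface DSC endpoints: identical masks give 1, separated masks 0 then 1", {
  m <- cube_mask(c(8, 8, 8), c(3, 3, 3), c(6, 6, 6))
  for (tau in c(0, 4, 8, 10)) expect_equal(surface_dsc(m, m, tau), 1)

  # single voxels 3 mm apart along an axis: every face-pair distance in [2, 4]
  arr_a <- array(0L, c(10, 5, 5)); arr_a[3, 3, 3] <- 1L
  arr_b <- array(0L, c(10, 5, 5)); arr_b[6, 3, 3] <- 1L
  a <- mask_of(arr_a); b <- mask_of(arr_b)
  expect_equal(surface_dsc(a, b, 4), 1)
  expect_equal(surface_dsc(a, b, 0), 0)

  # nested cubes: no coincident surfels at tau = 0, all matched at tau = 2
  outer7 <- cube_mask(c(11, 11, 11), c(3, 3, 3), c(9, 9, 9))
  inner5 <- cube_mask(c(11, 11, 11), c(4, 4, 4), c(8, 8, 8))
  expect_equal(surface_dsc(inner5, outer7, 0), 0)
  expect_equal(surface_dsc(inner5, outer7, 2), 1)
  expect_error(surface_dsc(a, b, -1), class = "segsim_parameter_error")
})

test_that("surface DSC matches the brute-force oracle and is non-decreasing in tau", {
  set.seed(61)
  taus <- c(0, 1, 2, 4, 8, 10)
  for (rep in 1:10) {
    a <- random_nonempty_mask(c(7, 7, 7), p = 0.3)
    b <- random_nonempty_mask(c(7, 7, 7), p = 0.3)
    vals <- vapply(taus, function(tau) surface_dsc(a, b, tau), numeric(1))
    orac <- vapply(taus, function(tau) oracle_surface_dsc(a, b, tau), numeric(1))
    expect_equal(vals, orac, tolerance = 1e-12)
    expect_true(all(diff(vals) >= -1e-15))
    expect_true(all(vals >= 0 & vals <= 1))
    # symmetric under swap
    expect_equal(surface_dsc(b, a, 2), surface_dsc(a, b, 2), tolerance = 1e-12)
    # reaches 1 for tau >= max pooled nearest distance (voxel-center bound is
    # looser than surfel distances by at most one voxel diagonal)
    dmax <- max(oracle_pooled_distances(a, b))
    expect_equal(surface_dsc(a, b, dmax + sqrt(3)), 1)
  }
})

test_that("at tau = 0, voxel-center surface DSC equals the coincident boundary fraction", {
  set.seed(62)
  for (rep in 1:5) {
    a <- random_nonempty_mask(c(7, 7, 7), p = 0.3)
    b <- random_nonempty_mask(c(7, 7, 7), p = 0.3)
    sa <- extract_boundary_3d(a, "voxel-center")
    sb <- extract_boundary_3d(b, "voxel-center")
    key <- function(p) paste(p[, 1], p[, 2], p[, 3])
    ka <- key(sa$positions); kb <- key(sb$positions)
    frac <- (sum(sa$weights[ka %in% kb]) + sum(sb$weights[kb %in% ka])) /
      (sum(sa$weights) + sum(sb$weights))
    expect_equal(surface_dsc(a, b, 0, mode = "voxel-center"), frac, tolerance = 1e-12)
  }
})

test_that("percentile Hausdorff pools both directions and interpolates linearly", {
  m <- cube_mask(c(8, 8, 8), c(3, 3, 3), c(6, 6, 6))
  for (p in c(95, 98, 99, 100)) expect_equal(hausdorff_percentile(m, m, p), 0)

  arr_a <- array(0L, c(10, 5, 5)); arr_a[3, 3, 3] <- 1L
  arr_b <- array(0L, c(10, 5, 5)); arr_b[6, 3, 3] <- 1L
  expect_equal(hausdorff_percentile(mask_of(arr_a), mask_of(arr_b), 100), 3)

  set.seed(63)
  for (rep in 1:8) {
    a <- random_nonempty_mask(c(10, 10, 10), p = 0.25)
    b <- random_nonempty_mask(c(10, 10, 10), p = 0.25)
    pooled <- oracle_pooled_distances(a, b)
    hds <- vapply(c(95, 98, 99, 100), function(p) hausdorff_percentile(a, b, p),
                  numeric(1))
    want <- c(quantile(pooled, c(.95, .98, .99), type = 7, names = FALSE), max(pooled))
    expect_equal(hds, want, tolerance = 1e-9)
    expect_true(all(diff(hds) >= -1e-12))  # HD(95) <= HD(98) <= HD(99) <= HD(100)
    expect_equal(hausdorff_percentile(b, a, 98), hds[2], tolerance = 1e-12)
  }
  expect_error(hausdorff_percentile(m, m, 0), class = "segsim_parameter_error")
  expect_error(hausdorff_percentile(m, m, 101), class = "segsim_parameter_error")
})

test_that("ASD averages the two directed means, not the pooled multiset", {
  m <- cube_mask(c(8, 8, 8), c(3, 3, 3), c(6, 6, 6))
  expect_equal(average_surface_distance(m, m), 0)

  # asymmetric element counts: directed means differ from the pooled mean
  arr_a <- array(0L, c(12, 7, 3)); arr_a[2, 2, 2] <- 1L
  arr_b <- array(0L, c(12, 7, 3)); arr_b[4, 2, 2] <- 1L; arr_b[4, 4, 2] <- 1L
  arr_b[8, 2, 2] <- 1L
  a <- mask_of(arr_a); b <- mask_of(arr_b)
  pa <- oracle_boundary_positions(a); pb <- oracle_boundary_positions(b)
  dab <- oracle_nn(pa, pb); dba <- oracle_nn(pb, pa)
  two_means <- (mean(dab) + mean(dba)) / 2
  pooled_mean <- mean(c(dab, dba))
  expect_false(isTRUE(all.equal(two_means, pooled_mean)))
  expect_equal(average_surface_distance(a, b), two_means, tolerance = 1e-12)
  expect_equal(average_surface_distance(b, a), two_means, tolerance = 1e-12)
})

test_that("APL counts corrected edge pixels absent from the auto edge", {
  sq <- cube_mask(c(14, 14, 3), c(3, 3, 2), c(12, 12, 2))
  expect_equal(added_path_length(sq, sq), 0L)

  e <- mask_of(array(0L, c(14, 14, 3)))
  sq5 <- cube_mask(c(14, 14, 3), c(2, 2, 2), c(6, 6, 2))
  expect_equal(added_path_length(e, sq5), 16L)  # whole perimeter is added

  # 10x10 square dilated by 1 -> 12x12: perimeters are disjoint, APL = 44
  a <- cube_mask(c(14, 14, 1), c(3, 3, 1), c(12, 12, 1))
  b <- cube_mask(c(14, 14, 1), c(2, 2, 1), c(13, 13, 1))
  expect_equal(added_path_length(a, b), 44L)
  expect_equal(false_negative_path_length(a, b), 44L)  # pure growth: nothing erased
})

test_that("FNPL excludes edge pixels created by shrinking edits", {
  # corrected strictly interior to auto: every corrected edge pixel is inside
  # the auto volume -> FNPL 0 while APL = corrected edge count
  a <- cube_mask(c(14, 14, 1), c(2, 2, 1), c(13, 13, 1))
  b <- cube_mask(c(14, 14, 1), c(4, 4, 1), c(11, 11, 1))
  expect_equal(added_path_length(a, b), 28L)
  expect_equal(false_negative_path_length(a, b), 0L)

  # nothing to erase when auto is empty
  e <- mask_of(array(0L, c(14, 14, 1)))
  expect_equal(false_negative_path_length(e, b), added_path_length(e, b))

  # mixed edit: dilate one side, erode the other; classify each corrected
  # edge pixel by brute force
  arr_a <- array(0L, c(20, 10, 1)); arr_a[5:12, 3:8, 1] <- 1L
  arr_b <- array(0L, c(20, 10, 1)); arr_b[7:14, 3:8, 1] <- 1L
  a2 <- mask_of(arr_a); b2 <- mask_of(arr_b)
  ea <- oracle_edges_2d(a2); eb <- oracle_edges_2d(b2)
  apl_oracle <- sum(eb & !ea)
  fnpl_oracle <- sum(eb & !ea & !(arr_a == 1L))
  expect_equal(added_path_length(a2, b2), apl_oracle)
  expect_equal(false_negative_path_length(a2, b2), fnpl_oracle)
  expect_lt(fnpl_oracle, apl_oracle)
})

test_that("0 <= FNPL <= APL <= corrected edge count on random pairs; APL(a,a) = 0", {
  set.seed(64)
  for (rep in 1:25) {
    a <- random_mask(c(8, 8, 4), p = runif(1, 0.1, 0.6))
    b <- random_mask(c(8, 8, 4), p = runif(1, 0.1, 0.6))
    apl <- added_path_length(a, b)
    fnpl <- false_negative_path_length(a, b)
    expect_true(fnpl >= 0L && fnpl <= apl)
    expect_true(apl <= extract_edges_2d(b)$total_count)
    expect_equal(added_path_length(a, a), 0L)
    expect_equal(false_negative_path_length(a, a), 0L)
  }
})

test_that("surface metrics reject empty masks and mismatched grids", {
  e <- mask_of(array(0L, c(6, 6, 6)))
  m <- cube_mask(c(6, 6, 6), c(2, 2, 2), c(4, 4, 4))
  expect_error(surface_dsc(e, m, 1), class = "segsim_empty_surface_error")
  expect_error(hausdorff_percentile(m, e, 95), class = "segsim_empty_surface_error")
  expect_error(average_surface_distance(e, e), class = "segsim_empty_surface_error")
  other <- cube_mask(c(6, 6, 7), c(2, 2, 2), c(4, 4, 4))
  expect_error(added_path_length(m, other), class = "segsim_geometry_error")
})
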