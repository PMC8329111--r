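# Fixture builders and independent brute-force oracles used across tests.
# The oracles are deliberately written as plain loops over voxels/pairs so
# they share no code path with the package implementation.

mask_of <- function(arr, spacing = c(1, 1, 1)) binary_mask(arr, spacing)

# Random binary lattice with given foreground probability.
random_mask <- function(dims, p = 0.3, spacing = c(1, 1, 1)) {
  arr <- array(runif(prod(dims)) < p, dims)
  binary_mask(arr, spacing)
}

# Random mask guaranteed nonempty.
random_nonempty_mask <- function(dims, p = 0.3, spacing = c(1, 1, 1)) {
  repeat {
    m <- random_mask(dims, p, spacing)
    if (n_foreground(m) > 0L) return(m)
  }
}

cube_mask <- function(dims, lo, hi, spacing = c(1, 1, 1)) {
  arr <- array(0L, dims)
  arr[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- 1L
  binary_mask(arr, spacing)
}

# --- brute-force oracles -----------------------------------------------------

# All-pairs directed nearest distances: builds the full squared-distance
# matrix in R and takes row minima (no shared code with the compiled path).
oracle_nn <- function(from, to) {
  d2 <- outer(from[, 1], to[, 1], "-")^2 +
        outer(from[, 2], to[, 2], "-")^2 +
        outer(from[, 3], to[, 3], "-")^2
  sqrt(d2[cbind(seq_len(nrow(d2)), max.col(-d2, ties.method = "first"))])
}

# Boundary voxels by scanning all 6 face neighbours of every voxel.
oracle_boundary_voxels <- function(mask) {
  d <- dim(mask$voxels); v <- mask$voxels
  out <- NULL
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (v[i, j, k] != 1L) next
    nb <- list(c(i - 1, j, k), c(i + 1, j, k), c(i, j - 1, k),
               c(i, j + 1, k), c(i, j, k - 1), c(i, j, k + 1))
    exposed <- any(vapply(nb, function(q) {
      any(q < 1) || q[1] > d[1] || q[2] > d[2] || q[3] > d[3] ||
        v[q[1], q[2], q[3]] == 0L
    }, logical(1)))
    if (exposed) out <- rbind(out, c(i, j, k))
  }
  out
}

# Count of exposed faces over all voxels (total face-surfel count).
oracle_exposed_faces <- function(mask) {
  d <- dim(mask$voxels); v <- mask$voxels
  n <- 0L
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (v[i, j, k] != 1L) next
    nb <- list(c(i - 1, j, k), c(i + 1, j, k), c(i, j - 1, k),
               c(i, j + 1, k), c(i, j, k - 1), c(i, j, k + 1))
    for (q in nb)
      if (any(q < 1) || q[1] > d[1] || q[2] > d[2] || q[3] > d[3] ||
          v[q[1], q[2], q[3]] == 0L) n <- n + 1L
  }
  n
}

# Per-slice 2D edge pixels via 4-neighbour scan.
oracle_edges_2d <- function(mask) {
  d <- dim(mask$voxels); v <- mask$voxels
  edge <- array(FALSE, d)
  for (k in seq_len(d[3])) for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    if (v[i, j, k] != 1L) next
    nb <- list(c(i - 1, j), c(i + 1, j), c(i, j - 1), c(i, j + 1))
    edge[i, j, k] <- any(vapply(nb, function(q) {
      any(q < 1) || q[1] > d[1] || q[2] > d[2] || v[q[1], q[2], k] == 0L
    }, logical(1)))
  }
  edge
}

# Voxel-center boundary positions in mm for a mask (oracle path).
oracle_boundary_positions <- function(mask) {
  idx <- oracle_boundary_voxels(mask)
  sweep(idx - 1, 2, mask$spacing, "*")
}

# Oracle Spearman rho and exact permutation p by full enumeration (n <= 5).
oracle_spearman <- function(x, y) {
  rho <- function(a, b) {
    ra <- rank(a); rb <- rank(b)
    sum((ra - mean(ra)) * (rb - mean(rb))) /
      sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
  }
  obs <- rho(x, y)
  perms <- all_perms(length(y))
  rhos <- apply(perms, 1, function(p) rho(x, y[p]))
  list(rho = obs, p = mean(abs(rhos) >= abs(obs) - 1e-12))
}

# All n! permutations of 1..n (recursive; used for n <= 5 enumeration).
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- setdiff(seq_len(n), k)
    cbind(k, matrix(rest[sub], nrow(sub)))
  }))
}
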