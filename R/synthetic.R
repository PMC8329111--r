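# Physical voxel-center coordinate grids (mm) as three vectors.
grid_coords <- function(dims, spacing) lapply(1:3, function(a) (seq_len(dims[a]) - 1) * spacing[a])

# Logical array of an axis-aligned ellipsoid given center/semi-axes in mm.
ellipsoid_fg <- function(dims, spacing, center, semi) {
  co <- grid_coords(dims, spacing)
  u <- lapply(1:3, function(a) ((co[[a]] - center[a]) / semi[a])^2)
  array(outer(outer(u[[1]], u[[2]], "+"), u[[3]], "+") <= 1, dims)
}

sphere_fg <- function(dims, spacing, center, r) ellipsoid_fg(dims, spacing, center, rep(r, 3))

base_shape_fg <- function(shape, dims, spacing) {
  ext <- dims * spacing
  mid <- (dims - 1) * spacing / 2
  switch(shape,
    ellipsoid = ellipsoid_fg(dims, spacing, mid, 0.35 * ext),
    box = {
      fg <- array(FALSE, dims)
      lo <- pmax(1L, round(dims * 0.2)); hi <- pmin(dims, round(dims * 0.8))
      fg[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
      fg
    },
    `two-lobe` = {
      off <- c(0.22 * ext[1], 0, 0)
      semi <- c(0.17, 0.3, 0.35) * ext
      ellipsoid_fg(dims, spacing, mid - off, semi) |
        ellipsoid_fg(dims, spacing, mid + off, semi)
    },
    segsim_stop(sprintf("unknown base shape '%s'", shape), "segsim_parameter_error"))
}

# 6-connectivity morphological dilation/erosion by k voxel steps.
dilate_fg <- function(fg, k) {
  for (i in seq_len(k)) {
    nb <- fg
    for (axis in 1:3) for (dir in c(-1L, 1L)) nb <- nb | neighbor_fg(fg, axis, dir)
    fg <- nb
  }
  fg
}
erode_fg <- function(fg, k) {
  for (i in seq_len(k)) {
    nb <- fg
    for (axis in 1:3) for (dir in c(-1L, 1L)) nb <- nb & neighbor_fg(fg, axis, dir)
    fg <- nb
  }
  fg
}

#' Specify a synthetic auto/corrected perturbation
#'
#' Describes how an "auto" segmentation is derived from a "corrected"
#' reference phantom: spherical blobs (defined in mm space, so anisotropy
#' aware) removed from the auto mask emulate regions the autosegmentation
#' missed (false negatives the human must add), blobs appended outside the
#' reference emulate auto false positives (the human erases them), and an
#' optional uniform boundary shift dilates (positive) or erodes (negative)
#' the auto mask. The default grid, 64 x 64 x 32 voxels at (1, 1, 3) mm,
#' mimics lung-CT anisotropy at desk scale.
#'
#' @param base_shape `"ellipsoid"`, `"box"`, or `"two-lobe"`.
#' @param grid_dims integer length-3 lattice dimensions.
#' @param spacing mm per voxel, length 3.
#' @param n_add_blobs number of blobs removed from the auto mask.
#' @param add_blob_radius_range mm range for their radii.
#' @param n_erase_blobs number of blobs appended to the auto mask.
#' @param erase_blob_radius_range mm range for their radii.
#' @param boundary_shift_px integer; > 0 dilates the auto mask by that many
#'   voxel steps, < 0 erodes.
#' @param seed RNG seed; a fixed seed gives bit-identical output.
#' @return a `perturbation_spec` list.
#' @export
perturbation_spec <- function(base_shape = "ellipsoid",
                              grid_dims = c(64, 64, 32),
                              spacing = c(1, 1, 3),
                              n_add_blobs = 2, add_blob_radius_range = c(4, 6),
                              n_erase_blobs = 1, erase_blob_radius_range = c(3, 5),
                              boundary_shift_px = 0, seed = 1L) {
  if (any(add_blob_radius_range <= 0) || any(erase_blob_radius_range <= 0))
    segsim_stop("blob radii must be positive", "segsim_parameter_error")
  structure(list(base_shape = base_shape, grid_dims = as.integer(grid_dims),
                 spacing = as.numeric(spacing),
                 n_add_blobs = as.integer(n_add_blobs),
                 add_blob_radius_range = add_blob_radius_range,
                 n_erase_blobs = as.integer(n_erase_blobs),
                 erase_blob_radius_range = erase_blob_radius_range,
                 boundary_shift_px = as.integer(boundary_shift_px),
                 seed = as.integer(seed)),
            class = "perturbation_spec")
}

# Sample a blob center near the reference boundary such that the sphere fits
# inside the physical lattice; bounded retries.
sample_blob <- function(fg, dims, spacing, r, inside, avoid, max_tries = 100L) {
  bnd <- array(FALSE, dims)
  for (axis in 1:3) for (dir in c(-1L, 1L))
    bnd <- bnd | (fg & !neighbor_fg(fg, axis, dir))
  idx <- which(bnd, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    segsim_stop("degenerate reference shape: no boundary", "segsim_generation_error")
  ext <- (dims - 1) * spacing
  for (try in seq_len(max_tries)) {
    ctr <- (idx[sample.int(nrow(idx), 1L), ] - 1) * spacing
    ctr <- pmin(pmax(ctr, r), ext - r)       # keep sphere inside the lattice
    if (any(ctr < r - 1e-9) || any(ctr > ext - r + 1e-9)) next
    blob <- sphere_fg(dims, spacing, ctr, r)
    blob <- if (inside) blob & fg & !avoid else blob & !fg & !avoid
    if (any(blob)) return(list(center = ctr, voxels = blob))
  }
  segsim_stop("could not place blob after bounded retries",
              "segsim_generation_error")
}

#' Generate one auto/corrected mask pair
#'
#' The corrected mask is the base phantom; the auto mask is the phantom with
#' the add-blobs removed, the erase-blobs appended, and the optional
#' boundary shift applied. A truth ledger records exactly which voxels
#' differ, so metric outputs can be checked against ground truth (e.g. with
#' no boundary shift, the false negative volume equals the ledger's
#' removed-voxel count).
#'
#' @param spec a [perturbation_spec].
#' @return list with `auto`, `corrected` ([binary_mask]s) and `truth`: a
#'   list with logical arrays `removed_from_auto`, `added_to_auto`, counts
#'   `n_removed`/`n_added`, and a per-blob `blobs` data.frame.
#' @export
make_pair <- function(spec) {
  stopifnot(inherits(spec, "perturbation_spec"))
  set.seed(spec$seed)
  dims <- spec$grid_dims; sp <- spec$spacing
  corrected_fg <- base_shape_fg(spec$base_shape, dims, sp)
  removed <- array(FALSE, dims); added <- array(FALSE, dims)
  blobs <- list()
  for (i in seq_len(spec$n_add_blobs)) {
    r <- runif(1, spec$add_blob_radius_range[1], spec$add_blob_radius_range[2])
    b <- sample_blob(corrected_fg, dims, sp, r, inside = TRUE, avoid = removed)
    removed <- removed | b$voxels
    blobs[[length(blobs) + 1L]] <- data.frame(kind = "add", r_mm = r,
                                              cx = b$center[1], cy = b$center[2],
                                              cz = b$center[3], n_voxels = sum(b$voxels))
  }
  for (i in seq_len(spec$n_erase_blobs)) {
    r <- runif(1, spec$erase_blob_radius_range[1], spec$erase_blob_radius_range[2])
    b <- sample_blob(corrected_fg, dims, sp, r, inside = FALSE, avoid = added)
    added <- added | b$voxels
    blobs[[length(blobs) + 1L]] <- data.frame(kind = "erase", r_mm = r,
                                              cx = b$center[1], cy = b$center[2],
                                              cz = b$center[3], n_voxels = sum(b$voxels))
  }
  auto_fg <- (corrected_fg & !removed) | added
  if (spec$boundary_shift_px > 0) auto_fg <- dilate_fg(auto_fg, spec$boundary_shift_px)
  if (spec$boundary_shift_px < 0) auto_fg <- erode_fg(auto_fg, -spec$boundary_shift_px)
  truth <- list(removed_from_auto = removed, added_to_auto = added,
                n_removed = sum(removed), n_added = sum(added),
                blobs = if (length(blobs)) do.call(rbind, blobs) else
                  data.frame(kind = character(), r_mm = numeric(), cx = numeric(),
                             cy = numeric(), cz = numeric(), n_voxels = integer()))
  list(auto = binary_mask(auto_fg, sp, source_path = "synthetic:auto"),
       corrected = binary_mask(corrected_fg, sp, source_path = "synthetic:corrected"),
       truth = truth)
}

#' Specify the simulated correction-time model
#'
#' Correction times are generated as a monotone noisy function of a chosen
#' driver metric: time = exp(log(intercept + slope * driver) + eps), with
#' eps ~ Normal(0, noise_sd) on the log scale. Lognormal noise keeps times
#' positive and right-skewed, mirroring the non-normal time distributions
#' such workflows produce. Defaults (5 min floor, 0.015 min per added-path
#' pixel, sd 0.25) put typical desk-scale phantom cohorts in the 5-50 min
#' range seen in thoracic correction workflows.
#'
#' @param driver_metric one of `"apl"`, `"fnv"`, `"fnpl"`,
#'   `"volumetric_dsc"`.
#' @param intercept minutes, > 0.
#' @param slope minutes per driver unit.
#' @param noise_sd log-scale noise SD; 0 makes time a deterministic
#'   monotone map of the driver.
#' @param seed RNG seed for the noise draws.
#' @return a `time_model_spec` list.
#' @export
time_model_spec <- function(driver_metric = "apl", intercept = 5,
                            slope = 0.015, noise_sd = 0.25, seed = 100L) {
  if (intercept <= 0) segsim_stop("intercept must be positive minutes",
                                  "segsim_parameter_error")
  structure(list(driver_metric = driver_metric, intercept = intercept,
                 slope = slope, noise_sd = noise_sd, seed = as.integer(seed)),
            class = "time_model_spec")
}

driver_value <- function(metric, auto, corrected) {
  switch(metric,
         apl = added_path_length(auto, corrected),
         fnpl = false_negative_path_length(auto, corrected),
         fnv = false_negative_volume(auto, corrected),
         volumetric_dsc = volumetric_dsc(auto, corrected),
         segsim_stop(sprintf("unknown driver metric '%s'", metric),
                     "segsim_parameter_error"))
}

#' Default per-case perturbation sampler
#'
#' Returns a sampler function(i, seed) -> [perturbation_spec] drawing the
#' edit structure of each case: blob counts vary widely (0-8 additions,
#' 0-3 erasures) while radii stay in a narrow band, so cohorts vary mostly
#' in the number of localized edits rather than total volume — the regime in
#' which path-length metrics and volume-overlap metrics decouple.
#'
#' @param grid_dims,spacing lattice geometry passed to every spec.
#' @param shapes base shapes sampled uniformly.
#' @param n_add_range,add_r integer range of add blobs and mm radius range.
#' @param n_erase_range,erase_r same for erase blobs.
#' @return function(i, seed) returning a [perturbation_spec].
#' @export
default_spec_sampler <- function(grid_dims = c(64, 64, 32), spacing = c(1, 1, 3),
                                 shapes = c("ellipsoid", "two-lobe", "box"),
                                 n_add_range = c(0, 8), add_r = c(4, 6),
                                 n_erase_range = c(0, 3), erase_r = c(3, 5)) {
  force(grid_dims); force(spacing); force(shapes)
  function(i, seed) {
    set.seed(seed)
    perturbation_spec(
      base_shape = sample(shapes, 1L),
      grid_dims = grid_dims, spacing = spacing,
      n_add_blobs = sample(seq(n_add_range[1], n_add_range[2]), 1L),
      add_blob_radius_range = add_r,
      n_erase_blobs = sample(seq(n_erase_range[1], n_erase_range[2]), 1L),
      erase_blob_radius_range = erase_r,
      boundary_shift_px = 0, seed = seed)
  }
}

#' Volume-budgeted perturbation sampler
#'
#' Like [default_spec_sampler()] but holds the total edit volume
#' approximately constant while the number of blobs varies: each case draws
#' a blob count and splits a fixed volume budget across equal-radius spheres
#' (r = (3V / (4 pi n))^(1/3)). In this regime volume-overlap metrics see
#' nearly the same error in every case while path-length metrics grow with
#' the number of localized edits — the regime in which the two metric
#' families decouple.
#'
#' @param grid_dims,spacing,shapes as in [default_spec_sampler()].
#' @param n_add_range integer range of add-blob counts (min >= 1).
#' @param total_volume_mm3 edit volume budget per case.
#' @return function(i, seed) returning a [perturbation_spec].
#' @export
fixed_volume_spec_sampler <- function(grid_dims = c(64, 64, 32),
                                      spacing = c(1, 1, 3),
                                      shapes = c("ellipsoid", "two-lobe"),
                                      n_add_range = c(1, 8),
                                      total_volume_mm3 = 2000) {
  force(grid_dims); force(spacing); force(shapes)
  function(i, seed) {
    set.seed(seed)
    n <- sample(seq(n_add_range[1], n_add_range[2]), 1L)
    r <- (3 * total_volume_mm3 / (4 * pi * n))^(1 / 3)
    perturbation_spec(
      base_shape = sample(shapes, 1L),
      grid_dims = grid_dims, spacing = spacing,
      n_add_blobs = n, add_blob_radius_range = c(r, r),
      n_erase_blobs = 0, erase_blob_radius_range = c(1, 1),
      boundary_shift_px = 0, seed = seed)
  }
}

#' Generate a synthetic cohort on disk
#'
#' Writes `n` NIfTI auto/corrected pairs plus a manifest CSV and a case
#' table CSV whose `correction_time` column follows the time model; the true
#' driver metric value of each case is kept in a `.true_driver` column for
#' recovery tests. All randomness derives from `seed`.
#'
#' @param n number of cases, >= 3.
#' @param spec_sampler function(i, seed) -> [perturbation_spec]; see
#'   [default_spec_sampler].
#' @param time_model a [time_model_spec].
#' @param dir output directory (created).
#' @param seed master seed.
#' @return list with `manifest` (data.frame), `cases` (data.frame) and
#'   `dir`; the CSVs are also written as manifest.csv / cases.csv.
#' @export
make_cohort <- function(n, spec_sampler = default_spec_sampler(),
                        time_model = time_model_spec(),
                        dir = tempfile("segsim_cohort"), seed = 1L) {
  if (n < 3L)
    segsim_stop("a cohort needs n >= 3 cases", "segsim_precondition_error")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  case_seeds <- sample.int(.Machine$integer.max - 1L, n)
  ids <- sprintf("case%03d", seq_len(n))
  auto_paths <- file.path(dir, paste0(ids, "_auto.nii.gz"))
  corr_paths <- file.path(dir, paste0(ids, "_corrected.nii.gz"))
  driver <- numeric(n); shape <- character(n); n_edits <- integer(n)
  for (i in seq_len(n)) {
    spec <- spec_sampler(i, case_seeds[i])
    pair <- make_pair(spec)
    save_mask(pair$auto, auto_paths[i])
    save_mask(pair$corrected, corr_paths[i])
    driver[i] <- driver_value(time_model$driver_metric, pair$auto, pair$corrected)
    shape[i] <- spec$base_shape
    n_edits[i] <- spec$n_add_blobs + spec$n_erase_blobs
  }
  set.seed(time_model$seed)
  eps <- rnorm(n, 0, time_model$noise_sd)
  times <- exp(log(time_model$intercept + time_model$slope * driver) + eps)
  manifest <- data.frame(case_id = ids, auto_path = auto_paths,
                         corrected_path = corr_paths, stringsAsFactors = FALSE)
  cases <- data.frame(case_id = ids, correction_time = times,
                      base_shape = shape, n_edits = n_edits,
                      .true_driver = driver, stringsAsFactors = FALSE)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  write.csv(cases, file.path(dir, "cases.csv"), row.names = FALSE)
  list(manifest = manifest, cases = cases, dir = dir)
}
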