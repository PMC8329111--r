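#' Construct a binary mask
#'
#' The unit of comparison throughout the package: a 3D lattice of 0/1 voxels
#' with a physical voxel spacing in mm along each axis. Axis 3 (the third
#' array dimension) is designated the axial/slice axis for all slice-wise
#' operations, matching the slice-wise workflow in which segmentations are
#' manually corrected.
#'
#' @param voxels 3D array; any nonzero value is treated as foreground.
#' @param spacing numeric length-3, mm per voxel along each axis; all > 0.
#' @param orientation anatomical orientation code of the source file (e.g.
#'   "RAS"), kept as provenance only — geometry uses spacing alone.
#' @param source_path provenance string.
#' @param nonorthogonal logical flag set when the source affine contained
#'   shear/rotation beyond axis permutation or flip.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(voxels, spacing = c(1, 1, 1), orientation = NA_character_,
                        source_path = NA_character_, nonorthogonal = FALSE) {
  if (length(dim(voxels)) != 3L)
    segsim_stop(sprintf("mask must be a 3D array, got %d dimension(s)",
                        length(dim(voxels))), "segsim_dim_error")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    segsim_stop("spacing must be three strictly positive finite values (mm)",
                "segsim_metadata_error")
  vox <- array(as.integer(voxels != 0), dim(voxels))
  structure(
    list(voxels = vox, spacing = spacing, orientation = orientation,
         source_path = source_path, nonorthogonal = isTRUE(nonorthogonal)),
    class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<binary_mask> %dx%dx%d voxels, spacing (%g, %g, %g) mm, %d foreground\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              n_foreground(x)))
  invisible(x)
}

#' @export
dim.binary_mask <- function(x) dim(x$voxels)

#' Number of foreground voxels
#' @param mask a `binary_mask`.
#' @return integer count.
#' @export
n_foreground <- function(mask) sum(mask$voxels)

#' Are two masks comparable?
#'
#' Metrics are only defined for masks on the same grid: identical lattice
#' dimensions and voxel spacing within relative tolerance. Mismatched pairs
#' are rejected rather than resampled, because resampling would change the
#' raw pixel-count metrics (APL, FNPL, FNV).
#'
#' @param a,b `binary_mask` objects.
#' @param tol relative spacing tolerance.
#' @return logical.
#' @export
masks_comparable <- function(a, b, tol = 1e-5) {
  identical(dim(a$voxels), dim(b$voxels)) &&
    all(abs(a$spacing - b$spacing) <= tol * pmax(abs(a$spacing), abs(b$spacing)))
}

assert_comparable <- function(a, b) {
  if (!inherits(a, "binary_mask") || !inherits(b, "binary_mask"))
    segsim_stop("inputs must be binary_mask objects", "segsim_type_error")
  if (!masks_comparable(a, b))
    segsim_stop("masks are not comparable: grids or spacings differ",
                "segsim_geometry_error")
  invisible(TRUE)
}

# TRUE iff the 3x3 direction block is an axis permutation with flips
# (exactly one nonzero per row and column, up to tolerance).
is_axis_aligned <- function(R, tol = 1e-4) {
  A <- abs(R)
  scale <- pmax(apply(A, 1, max), .Machine$double.eps)
  big <- A > tol * scale
  all(rowSums(big) == 1L) && all(colSums(big) == 1L)
}

#' Load a binary mask from a NIfTI file
#'
#' Reads a NIfTI-1/NIfTI-2 volume and binarizes it: voxels with source
#' intensity strictly greater than `threshold` become foreground. Spacing is
#' taken from the header pixel dimensions. Rotational/shear components of the
#' affine are ignored (distances between two masks on a shared grid are
#' unaffected by a common rigid transform); if present beyond an axis
#' permutation or flip, the mask is still loaded with `nonorthogonal = TRUE`
#' and a warning.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param threshold binarization threshold; source values > threshold map to 1.
#' @return A [binary_mask].
#' @export
load_mask <- function(path, threshold = 0.5) {
  if (!file.exists(path))
    segsim_stop(sprintf("cannot read mask: file not found: %s", path),
                "segsim_io_error")
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) segsim_stop(
                    sprintf("cannot read NIfTI file %s: %s", path, conditionMessage(e)),
                    "segsim_io_error"))
  d <- dim(img)
  if (length(d) != 3L)
    segsim_stop(sprintf("expected a 3D volume, got %dD in %s", length(d), path),
                "segsim_dim_error")
  pd <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(pd)) || any(pd <= 0))
    segsim_stop(sprintf("non-positive voxel spacing in header of %s", path),
                "segsim_metadata_error")
  xf <- RNifti::xform(img)
  nonorth <- !is_axis_aligned(xf[1:3, 1:3])
  if (nonorth)
    warning(sprintf("affine of %s has shear/rotation beyond axis permutation; using header spacing only", path))
  orient <- tryCatch(RNifti::orientation(img), error = function(e) NA_character_)
  binary_mask(as.array(img) > threshold, spacing = pd, orientation = orient,
              source_path = path, nonorthogonal = nonorth)
}

#' Save a binary mask as NIfTI-1
#'
#' Writes uint8 voxel data with the mask's spacing in the header; a save/load
#' round trip reproduces voxels bit-exactly and spacing to float32 precision.
#'
#' @param mask a [binary_mask].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
save_mask <- function(mask, path) {
  img <- RNifti::asNifti(mask$voxels)
  RNifti::pixdim(img) <- mask$spacing
  tryCatch(RNifti::writeNifti(img, path, datatype = "uint8"),
           error = function(e) segsim_stop(
             sprintf("cannot write %s: %s", path, conditionMessage(e)),
             "segsim_io_error"))
  invisible(path)
}

#' Read a case manifest
#'
#' A manifest is a CSV with header columns `case_id`, `auto_path`,
#' `corrected_path`, one row per case.
#'
#' @param path CSV path.
#' @return data.frame with validated columns.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path))
    segsim_stop(sprintf("manifest not found: %s", path), "segsim_io_error")
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("case_id", "auto_path", "corrected_path")
  missing <- setdiff(required, names(df))
  if (length(missing))
    segsim_stop(paste0("manifest is missing column(s): ",
                       paste(missing, collapse = ", ")), "segsim_schema_error")
  df$case_id <- as.character(df$case_id)
  if (anyDuplicated(df$case_id))
    segsim_stop("manifest has duplicated case_id values", "segsim_validation_error")
  if (any(!nzchar(df$auto_path)) || any(!nzchar(df$corrected_path)))
    segsim_stop("manifest has empty mask paths", "segsim_validation_error")
  df[required]
}
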