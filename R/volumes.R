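# Volumetric data model shared by every stage of the pipeline.
#
# Convention: 0-padded 1-based voxel indices, axis order
# (x = left-right, y = anterior-posterior, z = inferior-superior).
# All masks and maps live on the grid of the baseline ADC volume.

#' Construct a scalar volume
#'
#' A `scalar_volume` is a 3D map (ADC, CBF, CBV, MTT, Tmax or a relative
#' counterpart) on a regular voxel grid with millimetre spacing. Background
#' or otherwise invalid voxels are stored as `NA`, never as silent zeros, so
#' that downstream divisions cannot pick them up unnoticed.
#'
#' @param values 3D numeric array; `NA` marks invalid/background voxels.
#' @param spacing_mm Voxel edge lengths in mm, length-3, strictly positive.
#' @param units Free-text physical units, e.g. `"mm^2/s"`, `"s"`,
#'   `"dimensionless"`.
#' @return An object of class `scalar_volume` with elements `values`,
#'   `spacing_mm` and `units`.
#' @export
scalar_volume <- function(values, spacing_mm = c(1, 1, 1), units = "") {
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("'values' must be a 3D array, got ", length(dim(values)), " dims")
  if (any(dim(values) < 1L)) stop("all three dimensions must be >= 1")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0))
    stop("'spacing_mm' must be three strictly positive finite numbers")
  structure(list(values = values, spacing_mm = spacing_mm, units = units),
            class = "scalar_volume")
}

#' @export
print.scalar_volume <- function(x, ...) {
  cat("<scalar_volume> ", paste(dim(x$values), collapse = " x "),
      " voxels @ ", paste(x$spacing_mm, collapse = "x"), " mm",
      if (nzchar(x$units)) paste0(" [", x$units, "]"), "\n", sep = "")
  cat("  valid voxels: ", sum(!is.na(x$values)), "\n", sep = "")
  invisible(x)
}

#' Construct a binary mask
#'
#' A `binary_mask` is a region of interest (infarct core, penumbra,
#' unaffected tissue, CSF, brain, hemisphere) on the same grid as its parent
#' volume.
#'
#' @param values 3D logical array (coerced with `NA` treated as `FALSE`).
#' @param spacing_mm Voxel spacing in mm, as in [scalar_volume()].
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(values, spacing_mm = c(1, 1, 1)) {
  values <- as.array(values)
  if (length(dim(values)) != 3L) stop("'values' must be a 3D array")
  v <- array(FALSE, dim(values))
  v[which(values != 0)] <- TRUE   # NA -> FALSE
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0))
    stop("'spacing_mm' must be three strictly positive finite numbers")
  structure(list(values = v, spacing_mm = spacing_mm), class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat("<binary_mask> ", paste(dim(x$values), collapse = " x "),
      " voxels, ", sum(x$values), " set\n", sep = "")
  invisible(x)
}

#' Number of voxels set in a mask
#' @param mask A [binary_mask()].
#' @return Integer voxel count.
#' @export
mask_count <- function(mask) sum(mask$values)

#' Mask volume in millilitres
#' @param mask A [binary_mask()].
#' @return Volume in mL (voxel count times voxel volume).
#' @export
mask_volume_ml <- function(mask) {
  mask_count(mask) * prod(mask$spacing_mm) / 1000
}

#' Dice similarity coefficient between two masks
#' @param a,b Two [binary_mask()] objects on the same grid.
#' @return Dice coefficient in \[0, 1\]; `NaN` when both masks are empty.
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(identical(dim(a$values), dim(b$values)))
  2 * sum(a$values & b$values) / (sum(a$values) + sum(b$values))
}

same_grid <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(a$spacing_mm, b$spacing_mm))
}

#' Read a 3D NIfTI volume
#'
#' Reads a NIfTI-1 file into a [scalar_volume()], taking the voxel spacing
#' from the header. 4D files (e.g. DSC time series) are rejected here; use
#' [read_dynamic_series()] for those.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param units Units to attach to the returned volume.
#' @return A [scalar_volume()].
#' @export
read_volume <- function(path, units = "") {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3D volume, got ", length(d), "D (4D not allowed here)")
  sp <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0))
    stop("non-finite or non-positive voxel spacing in header")
  v <- as.array(img)
  attributes(v) <- list(dim = dim(v))
  scalar_volume(v, spacing_mm = sp, units = units)
}

#' Write a scalar volume to NIfTI
#'
#' @param vol A [scalar_volume()]; `NA` voxels are written as 0.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param datatype NIfTI on-disk datatype; `"float"` (32-bit) by default.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, datatype = "float") {
  v <- vol$values
  v[is.na(v)] <- 0
  img <- RNifti::asNifti(v)
  RNifti::pixdim(img) <- vol$spacing_mm
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Read a binary mask from NIfTI
#' @param path Path to a mask file (any nonzero voxel is in the mask).
#' @return A [binary_mask()].
#' @export
read_mask <- function(path) {
  vol <- read_volume(path)
  binary_mask(vol$values != 0, spacing_mm = vol$spacing_mm)
}

#' Write a binary mask to NIfTI as uint8 \{0,1\}
#' @param mask A [binary_mask()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  img <- RNifti::asNifti(array(as.integer(mask$values), dim(mask$values)))
  RNifti::pixdim(img) <- mask$spacing_mm
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' Split a brain mask into hemispheres at the mid-sagittal grid plane
#'
#' The left-right axis is the first array axis; the midline is its grid
#' midpoint (for an odd extent the midline column goes to the left half).
#' This is adequate for head-centred phantoms and for data already aligned
#' to a symmetric grid; no midline estimation is attempted.
#'
#' @param brain Brain [binary_mask()], nonempty.
#' @param affected_side `"left"` or `"right"`: the hemisphere containing the
#'   ischemic lesion. The other hemisphere supplies the contralateral
#'   normalisation reference.
#' @return A `hemisphere_partition`: list with `left`, `right`
#'   ([binary_mask()]s partitioning `brain`) and `affected_side`.
#' @export
split_hemispheres <- function(brain, affected_side = c("left", "right")) {
  affected_side <- match.arg(affected_side)
  if (mask_count(brain) == 0L) stop("empty brain mask")
  d <- dim(brain$values)
  nx_left <- ceiling(d[1] / 2)
  xi <- slice.index(brain$values, 1)
  left <- brain$values & (xi <= nx_left)
  right <- brain$values & (xi > nx_left)
  structure(list(left = binary_mask(left, brain$spacing_mm),
                 right = binary_mask(right, brain$spacing_mm),
                 affected_side = affected_side),
            class = "hemisphere_partition")
}

#' Affected / contralateral hemisphere masks of a partition
#' @param hemis A `hemisphere_partition` from [split_hemispheres()].
#' @return A [binary_mask()].
#' @export
affected_hemisphere <- function(hemis) {
  if (hemis$affected_side == "left") hemis$left else hemis$right
}

#' @rdname affected_hemisphere
#' @export
contralateral_hemisphere <- function(hemis) {
  if (hemis$affected_side == "left") hemis$right else hemis$left
}

#' Brain mask from an ADC map
#'
#' Stand-in for a dedicated brain segmentation: voxels whose ADC lies in a
#' physiologically plausible range are labelled brain. The window keeps CSF
#' (high ADC, excluded later by the CSF mask) and excludes background (zero
#' or implausibly high apparent diffusion).
#'
#' @param adc ADC [scalar_volume()] in mm^2/s.
#' @param lower,upper Physiologic ADC window in mm^2/s; voxels with
#'   `lower < adc < upper` are brain.
#' @return Brain [binary_mask()].
#' @export
brain_mask_from_adc <- function(adc, lower = 1e-6, upper = 3500e-6) {
  v <- adc$values
  m <- !is.na(v) & v > lower & v < upper
  if (!any(m)) stop("all-background input: no voxel in the ADC brain window")
  binary_mask(m, spacing_mm = adc$spacing_mm)
}
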