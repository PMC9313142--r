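#' SUV volume container
#'
#' A minimal container for a 3D PET volume already calibrated to standardized
#' uptake values (SUV, here normalized to lean body mass, so dimensionless).
#' Arrays are stored in (z, y, x) axis order with voxel spacing in mm per
#' axis; the physical center of voxel index `i` (1-based) along an axis with
#' spacing `s` is at `(i - 0.5) * s` mm.
#'
#' @param values 3D numeric array of SUV values, axis order (z, y, x).
#'   Values must be finite and non-negative.
#' @param spacing numeric vector of voxel spacing in mm, `(dz, dy, dx)`;
#'   a scalar is recycled to all three axes.
#' @return an object of class `suv_volume` with elements `values` and
#'   `spacing`.
#' @examples
#' vol <- suv_volume(array(1, c(10, 10, 10)), spacing = 2)
#' voxel_volume_ml(vol)
#' @export
suv_volume <- function(values, spacing) {
  values <- unclass(values)
  if (length(dim(values)) != 3L)
    abort("'values' must be a 3D array (z, y, x)")
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    abort("voxel spacing must be positive and finite (mm)")
  if (any(!is.finite(values)))
    abort("SUV values must be finite")
  if (any(values < 0))
    abort("SUV values must be non-negative")
  structure(list(values = values, spacing = spacing), class = "suv_volume")
}

#' @export
print.suv_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("SUV volume: %d x %d x %d voxels (z,y,x), spacing %s mm\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = " x ")))
  cat(sprintf("  SUV range: %.3f - %.3f\n", min(x$values), max(x$values)))
  invisible(x)
}

#' Voxel volume of an SUV volume in mL
#'
#' @param vol an `suv_volume`.
#' @return voxel volume in mL (spacing product in mm^3 divided by 1000).
#' @export
voxel_volume_ml <- function(vol) {
  stopifnot(inherits(vol, "suv_volume"))
  prod(vol$spacing) / 1000
}

## physical centers (mm) of the voxels at 1-based array indices `ind`
## (n x 3 matrix, (z,y,x)); returns an n x 3 matrix in mm
voxel_centers_mm <- function(ind, spacing) {
  sweep(ind - 0.5, 2, spacing, `*`)
}

#' Read an SUV volume from a NIfTI file
#'
#' Reads a NIfTI image (voxel data interpreted as SUV) and reorders axes to
#' the internal (z, y, x) convention. Voxel spacing is taken from the header.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return an [suv_volume].
#' @export
read_suv_volume <- function(path) {
  if (!file.exists(path)) abort("missing artifact: ", path)
  img <- RNifti::readNifti(path)
  arr <- aperm(as.array(img), c(3, 2, 1))
  sp <- rev(RNifti::pixdim(img)[1:3])
  suv_volume(arr, sp)
}

#' Write an SUV volume to a NIfTI file
#'
#' Axes are reordered from the internal (z, y, x) convention to NIfTI's
#' (x, y, z); spacing goes into the header pixdim.
#'
#' @param vol an [suv_volume] (or a plain 3D array for label volumes).
#' @param path output path, `.nii` or `.nii.gz`.
#' @param spacing spacing override in mm, required when `vol` is a bare array.
#' @return `path`, invisibly.
#' @export
write_suv_volume <- function(vol, path, spacing = NULL) {
  if (inherits(vol, "suv_volume")) {
    arr <- vol$values
    spacing <- vol$spacing
  } else {
    arr <- vol
    if (is.null(spacing)) abort("'spacing' required for bare arrays")
    spacing <- rep_len(as.numeric(spacing), 3L)
  }
  img <- RNifti::asNifti(aperm(arr, c(3, 2, 1)))
  RNifti::pixdim(img) <- rev(spacing)
  RNifti::writeNifti(img, path)
  invisible(path)
}
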