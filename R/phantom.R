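#' Lesion specification for a synthetic PET phantom
#'
#' Describes one ellipsoidal lesion with a plateau SUV. Sites follow the
#' organ categories used in metastatic prostate cancer reads: the primary
#' prostate tumor plus lymph-node, bone and visceral metastases.
#'
#' @param center numeric (z, y, x) center in mm.
#' @param radii ellipsoid semi-axes in mm; a scalar gives a sphere.
#' @param intensity plateau SUV inside the lesion (dimensionless, >= 0).
#' @param site one of `"prostate"`, `"lymph_node"`, `"bone"`, `"visceral"`.
#' @return a `lesion_spec` list.
#' @export
lesion_spec <- function(center, radii, intensity,
                        site = c("prostate", "lymph_node", "bone", "visceral")) {
  site <- match.arg(site)
  center <- as.numeric(center)
  radii <- rep_len(as.numeric(radii), 3L)
  if (length(center) != 3L || any(!is.finite(center)))
    abort("lesion center must be 3 finite mm coordinates (z,y,x)")
  if (any(radii <= 0)) abort("lesion radii must be positive")
  if (!is_scalar_num(intensity) || intensity < 0)
    abort("lesion intensity must be a non-negative SUV")
  structure(list(center = center, radii = radii,
                 intensity = intensity, site = site),
            class = "lesion_spec")
}

#' Phantom specification
#'
#' Defines the synthetic measurement substrate the quantification stage is
#' exercised on: a noisy background, an aortic blood-pool cylinder (the
#' PERCIST reference region; 30 mm long by default) and a list of lesions
#' with known geometry and plateau intensity.
#'
#' @param grid_shape voxels per axis, (z, y, x).
#' @param spacing mm per axis; scalar recycled.
#' @param background_mean,background_sd background SUV distribution
#'   (normal, clipped at 0).
#' @param aorta list with elements `center` (mm, z/y/x), `axis` ("z", "y" or
#'   "x"), `diameter` and `length` (mm), `mean` and `sd` (SUV). Defaults are
#'   filled in for missing elements (10 mm diameter, 30 mm length).
#' @param lesions list of [lesion_spec] objects.
#' @param smoothing_fwhm optional Gaussian smoothing FWHM in mm (0 = off).
#'   Smoothing emulates partial-volume blur and is off by default so that
#'   plateau intensities remain exact.
#' @param seed integer seed for the noise streams.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(grid_shape = c(40, 40, 40), spacing = 2,
                         background_mean = 0.3, background_sd = 0.05,
                         aorta = list(), lesions = list(),
                         smoothing_fwhm = 0, seed = 1L) {
  spacing <- rep_len(as.numeric(spacing), 3L)
  grid_shape <- as.integer(rep_len(grid_shape, 3L))
  if (any(grid_shape < 1)) abort("grid_shape must be positive")
  if (any(spacing <= 0)) abort("spacing must be positive")
  if (background_sd < 0 || background_mean < 0)
    abort("background parameters must be non-negative")
  extent <- grid_shape * spacing
  ao <- utils::modifyList(list(center = extent / 2, axis = "z",
                               diameter = 10, length = 30,
                               mean = 2.0, sd = 0.1), aorta)
  if (ao$sd < 0 || ao$mean < 0 || ao$diameter <= 0 || ao$length <= 0)
    abort("invalid aorta parameters")
  lesions <- lapply(lesions, function(l) {
    if (!inherits(l, "lesion_spec")) abort("lesions must be lesion_spec objects")
    lo <- l$center - l$radii
    hi <- l$center + l$radii
    if (any(lo < 0) || any(hi > extent))
      abort("lesion extends outside the grid")
    l
  })
  structure(list(grid_shape = grid_shape, spacing = spacing,
                 background_mean = background_mean,
                 background_sd = background_sd,
                 aorta = ao, lesions = lesions,
                 smoothing_fwhm = smoothing_fwhm, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a synthetic PET phantom with ground truth
#'
#' Builds an SUV volume from a [phantom_spec]: background voxels are drawn
#' from a normal distribution clipped at zero, aorta voxels from their own
#' normal distribution, and lesion voxels are set to the plateau intensity
#' (noise-free), optionally followed by Gaussian smoothing. A voxel belongs
#' to a shape iff its center lies inside the analytic shape. The returned
#' ground truth labels each lesion with a distinct id; true volumes are
#' voxel counts times the voxel volume.
#'
#' Lesion geometry is independent of the noise seed: two runs with different
#' seeds produce identical ground-truth masks.
#'
#' @param spec a [phantom_spec].
#' @return a `pet_phantom` list with elements `volume` ([suv_volume]),
#'   `labels` (integer array, 0 = background, lesion ids 1..n),
#'   `aorta_mask` (logical array), `truth` (per-lesion data.frame with
#'   discretized and analytic volumes in mL) and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape
  sp <- spec$spacing
  vox_ml <- prod(sp) / 1000

  masks <- lapply(spec$lesions, function(l)
    ellipsoid_mask(d, sp, l$center, l$radii))
  labels <- array(0L, d)
  for (i in seq_along(masks)) {
    if (any(labels[masks[[i]]] != 0L))
      abort("lesions overlap: ground truth would be ambiguous")
    labels[masks[[i]]] <- i
  }
  ao_mask <- cylinder_mask(d, sp, spec$aorta$center, spec$aorta$axis,
                           spec$aorta$diameter, spec$aorta$length)
  if (!any(ao_mask)) abort("aorta cylinder contains no voxel centers")

  set.seed(derive_seed(spec$seed, 11L))
  vals <- array(pmax(stats::rnorm(prod(d), spec$background_mean,
                                  spec$background_sd), 0), d)
  set.seed(derive_seed(spec$seed, 12L))
  vals[ao_mask] <- pmax(stats::rnorm(sum(ao_mask), spec$aorta$mean,
                                     spec$aorta$sd), 0)
  for (i in seq_along(masks)) vals[masks[[i]]] <- spec$lesions[[i]]$intensity
  if (spec$smoothing_fwhm > 0)
    vals <- pmax(gaussian_smooth(vals, spec$smoothing_fwhm, sp), 0)

  truth <- data.frame(
    lesion_id = seq_along(masks),
    site = vapply(spec$lesions, `[[`, "", "site"),
    intensity = vapply(spec$lesions, `[[`, 0, "intensity"),
    n_voxels = vapply(masks, sum, 0L),
    true_volume_ml = vapply(masks, sum, 0L) * vox_ml,
    analytic_volume_ml = vapply(spec$lesions, function(l)
      4 / 3 * pi * prod(l$radii) / 1000, 0),
    center_z = vapply(spec$lesions, function(l) l$center[1], 0),
    center_y = vapply(spec$lesions, function(l) l$center[2], 0),
    center_x = vapply(spec$lesions, function(l) l$center[3], 0),
    stringsAsFactors = FALSE
  )
  structure(list(volume = suv_volume(vals, sp), labels = labels,
                 aorta_mask = ao_mask, truth = truth, spec = spec),
            class = "pet_phantom")
}

#' @export
print.pet_phantom <- function(x, ...) {
  cat(sprintf("PET phantom: %s voxels, %d lesion(s)\n",
              paste(x$spec$grid_shape, collapse = "x"), nrow(x$truth)))
  if (nrow(x$truth))
    print(x$truth[, c("lesion_id", "site", "intensity", "true_volume_ml")])
  invisible(x)
}

#' Write a phantom to disk (NIfTI volume + label volume + truth CSV)
#'
#' @param phantom a `pet_phantom`.
#' @param prefix output path prefix; writes `<prefix>.nii.gz`,
#'   `<prefix>_labels.nii.gz` and `<prefix>_truth.csv`.
#' @return named character vector of the written paths, invisibly.
#' @export
write_phantom <- function(phantom, prefix) {
  stopifnot(inherits(phantom, "pet_phantom"))
  paths <- c(volume = paste0(prefix, ".nii.gz"),
             labels = paste0(prefix, "_labels.nii.gz"),
             truth = paste0(prefix, "_truth.csv"))
  write_suv_volume(phantom$volume, paths["volume"])
  write_suv_volume(phantom$labels, paths["labels"],
                   spacing = phantom$volume$spacing)
  utils::write.csv(phantom$truth, paths["truth"], row.names = FALSE)
  invisible(paths)
}
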