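## Analytic shape digitization. A voxel belongs to a shape iff its *center*
## lies inside (boundary inclusive); this keeps ground truth deterministic
## and lets tests recompute every mask by brute force.

## logical mask of an axis-aligned ellipsoid; center/radii in mm, (z,y,x)
ellipsoid_mask <- function(dim, spacing, center, radii) {
  radii <- rep_len(as.numeric(radii), 3L)
  ax <- lapply(1:3, function(a) {
    ((seq_len(dim[a]) - 0.5) * spacing[a] - center[a]) / radii[a]
  })
  ## outer sum of squared normalized coordinates, (z,y,x) array
  z2 <- ax[[1]]^2
  y2 <- ax[[2]]^2
  x2 <- ax[[3]]^2
  arr <- outer(outer(z2, y2, `+`), x2, `+`)
  arr <= 1
}

## logical mask of a cylinder with axis parallel to a grid axis
## center in mm (z,y,x); axis one of "z","y","x"; diameter/length in mm
cylinder_mask <- function(dim, spacing, center, axis = "z",
                          diameter = 10, length = 30) {
  ax_id <- match(axis, c("z", "y", "x"))
  if (is.na(ax_id)) abort("cylinder axis must be one of 'z','y','x'")
  coords <- lapply(1:3, function(a) (seq_len(dim[a]) - 0.5) * spacing[a] - center[a])
  along <- abs(coords[[ax_id]]) <= length / 2
  rad <- setdiff(1:3, ax_id)
  r2 <- outer(coords[[rad[1]]]^2, coords[[rad[2]]]^2, `+`) <= (diameter / 2)^2
  ## assemble in (z,y,x) order
  arr <- array(FALSE, dim)
  if (ax_id == 1) {
    for (k in which(along)) arr[k, , ] <- r2
  } else if (ax_id == 2) {
    for (k in which(along)) arr[, k, ] <- r2
  } else {
    for (k in which(along)) arr[, , k] <- r2
  }
  arr
}

## integer voxel offsets (n x 3, (dz,dy,dx)) whose centers lie within a
## sphere of the given diameter (mm) around a voxel center
sphere_offsets <- function(spacing, diameter_mm) {
  r <- diameter_mm / 2
  nmax <- floor(r / spacing)
  g <- as.matrix(expand.grid(dz = -nmax[1]:nmax[1],
                             dy = -nmax[2]:nmax[2],
                             dx = -nmax[3]:nmax[3]))
  d2 <- (g[, 1] * spacing[1])^2 + (g[, 2] * spacing[2])^2 + (g[, 3] * spacing[3])^2
  g[d2 <= r^2, , drop = FALSE]
}

## separable Gaussian blur (optional partial-volume emulation); fwhm in mm
gaussian_smooth <- function(arr, fwhm_mm, spacing) {
  fwhm <- rep_len(as.numeric(fwhm_mm), 3L)
  if (all(fwhm <= 0)) return(arr)
  for (a in 1:3) {
    if (fwhm[a] <= 0) next
    sigma <- fwhm[a] / (2 * sqrt(2 * log(2))) / spacing[a]
    hw <- max(1L, ceiling(3 * sigma))
    k <- exp(-0.5 * ((-hw:hw) / sigma)^2)
    k <- k / sum(k)
    arr <- convolve_axis(arr, k, a)
  }
  arr
}

## convolve along axis `a` with kernel `k` (odd length), replicate padding
convolve_axis <- function(arr, k, a) {
  d <- dim(arr)
  hw <- (length(k) - 1L) / 2L
  perm <- c(a, setdiff(1:3, a))
  m <- aperm(arr, perm)
  dm <- dim(m)
  m <- matrix(m, nrow = dm[1])
  n <- nrow(m)
  pad <- rbind(m[rep(1L, hw), , drop = FALSE], m, m[rep(n, hw), , drop = FALSE])
  out <- matrix(0, n, ncol(m))
  for (j in seq_along(k)) out <- out + k[j] * pad[(j - 1L) + seq_len(n), , drop = FALSE]
  out <- array(out, dm)
  aperm(out, order(perm))
}
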