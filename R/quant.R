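#' Lean body mass (Janmahasatian formula, male)
#'
#' SUV normalization to lean body mass (SUL) uses the James/Janmahasatian
#' family of formulas; the male Janmahasatian form is used here:
#' `LBM = 9270 * W / (6680 + 216 * BMI)` with `BMI = W / height_m^2`.
#' The study population is male, so only the male formula is provided;
#' volumes may alternatively arrive already normalized, bypassing this.
#'
#' @param weight_kg body weight in kg (> 0).
#' @param height_cm height in cm (> 0).
#' @param sex must be `"male"`.
#' @return lean body mass in kg.
#' @examples
#' lean_body_mass(80, 180)  # 61.73 kg
#' @export
lean_body_mass <- function(weight_kg, height_cm, sex = "male") {
  if (!identical(sex, "male"))
    abort("only the male lean-body-mass formula is implemented")
  if (any(!is.finite(weight_kg)) || any(!is.finite(height_cm)) ||
      any(weight_kg <= 0) || any(height_cm <= 0))
    abort("weight and height must be positive")
  bmi <- weight_kg / (height_cm / 100)^2
  9270 * weight_kg / (6680 + 216 * bmi)
}

#' Blood-pool reference statistics in an aortic cylinder VOI
#'
#' Computes mean, SD (denominator n-1) and the peak-sphere statistic over
#' the voxels whose centers lie inside a cylindrical VOI in the aorta
#' (30 mm long by default, axis-aligned). The peak statistic constrains
#' sphere centers to the cylinder; the averaging sphere itself may extend
#' beyond the cylinder into surrounding tissue but not outside the grid.
#'
#' @param volume an [suv_volume].
#' @param center cylinder center in mm, (z, y, x).
#' @param axis cylinder axis, one of `"z"`, `"y"`, `"x"`.
#' @param diameter cylinder diameter in mm (default 10).
#' @param length cylinder length in mm (default 30).
#' @param sphere_diameter_mm peak-sphere diameter in mm (default 12).
#' @return an `aorta_stats` list: `suv_peak`, `suv_mean`, `suv_sd`,
#'   `voi_voxel_count`, plus the cylinder mask.
#' @export
aorta_stats <- function(volume, center, axis = "z", diameter = 10,
                        length = 30, sphere_diameter_mm = 12) {
  stopifnot(inherits(volume, "suv_volume"))
  d <- dim(volume$values)
  sp <- volume$spacing
  ## the VOI must sit fully inside the grid
  ax_id <- match(axis, c("z", "y", "x"))
  if (is.na(ax_id)) abort("cylinder axis must be one of 'z','y','x'")
  half <- rep(diameter / 2, 3)
  half[ax_id] <- length / 2
  if (any(center - half < 0) || any(center + half > d * sp))
    abort("aorta cylinder extends outside the grid")
  mask <- cylinder_mask(d, sp, center, axis, diameter, length)
  nvox <- sum(mask)
  if (nvox == 0) abort("aorta VOI is empty")
  if (nvox < 2) abort("aorta VOI has a single voxel; SD undefined")
  vals <- volume$values[mask]
  pk <- suv_peak(volume, mask, sphere_diameter_mm)
  structure(list(suv_peak = as.numeric(pk), suv_mean = mean(vals),
                 suv_sd = stats::sd(vals), voi_voxel_count = nvox,
                 mask = mask),
            class = "aorta_stats")
}

#' @export
print.aorta_stats <- function(x, ...) {
  cat(sprintf(
    "Aorta VOI: %d voxels, SUVmean %.3f, SD %.3f, SUVpeak %.3f\n",
    x$voi_voxel_count, x$suv_mean, x$suv_sd, x$suv_peak))
  invisible(x)
}

#' PERCIST-style segmentation threshold
#'
#' `T = 1.5 * aorta SUVpeak + 2 * aorta SD`.
#'
#' @param stats an [aorta_stats] object, or a list with `suv_peak` and
#'   `suv_sd`.
#' @return the threshold in SUV units.
#' @export
compute_threshold <- function(stats) {
  if (!all(c("suv_peak", "suv_sd") %in% names(stats)))
    abort("'stats' must carry suv_peak and suv_sd")
  if (stats$suv_sd < 0 || stats$suv_peak < 0)
    abort("invalid aorta statistics")
  1.5 * stats$suv_peak + 2 * stats$suv_sd
}

#' Peak standardized uptake value (SUVpeak)
#'
#' The maximum, over averaging-sphere centers placed at voxel centers
#' inside `mask`, of the mean SUV within a sphere of the given diameter
#' (1.2 cm by default, ~1 cm^3, following the PERCIST tradition). Voxels
#' belong to the sphere if their centers lie within it. The sphere may
#' extend outside the mask but not outside the grid: centers whose sphere
#' would leave the grid are excluded; if no center admits a full sphere
#' (mask hugging the grid boundary), boundary-truncated spheres over all
#' mask centers are used instead. Ties are broken by the lowest (z, y, x)
#' center.
#'
#' @param volume an [suv_volume].
#' @param mask logical array (same dim) or integer vector of linear voxel
#'   indices marking eligible sphere centers.
#' @param sphere_diameter_mm averaging-sphere diameter in mm.
#' @return SUVpeak (numeric scalar) with attribute `center`, the (z, y, x)
#'   index of the winning sphere center.
#' @export
suv_peak <- function(volume, mask, sphere_diameter_mm = 12) {
  stopifnot(inherits(volume, "suv_volume"))
  d <- dim(volume$values)
  idx <- if (is.logical(mask)) which(mask) else as.integer(mask)
  if (length(idx) == 0) abort("empty mask")
  co <- arrayInd(idx, d)
  off <- sphere_offsets(volume$spacing, sphere_diameter_mm)
  nmax <- apply(abs(off), 2, max)
  full <- co[, 1] > nmax[1] & co[, 1] <= d[1] - nmax[1] &
          co[, 2] > nmax[2] & co[, 2] <= d[2] - nmax[2] &
          co[, 3] > nmax[3] & co[, 3] <= d[3] - nmax[3]
  vals <- volume$values
  if (any(full)) {
    cf <- co[full, , drop = FALSE]
    lin <- cf[, 1] + (cf[, 2] - 1) * d[1] + (cf[, 3] - 1) * d[1] * d[2]
    shift <- off[, 1] + off[, 2] * d[1] + off[, 3] * d[1] * d[2]
    s <- numeric(length(lin))
    for (sh in shift) s <- s + vals[lin + sh]
    means <- s / nrow(off)
    centers <- cf
  } else {
    ## truncated spheres: average over the in-grid part only
    s <- numeric(nrow(co))
    cnt <- numeric(nrow(co))
    for (j in seq_len(nrow(off))) {
      zz <- co[, 1] + off[j, 1]; yy <- co[, 2] + off[j, 2]
      xx <- co[, 3] + off[j, 3]
      ok <- zz >= 1 & zz <= d[1] & yy >= 1 & yy <= d[2] & xx >= 1 & xx <= d[3]
      lin <- zz[ok] + (yy[ok] - 1) * d[1] + (xx[ok] - 1) * d[1] * d[2]
      s[ok] <- s[ok] + vals[lin]
      cnt[ok] <- cnt[ok] + 1
    }
    means <- s / cnt
    centers <- co
  }
  ord <- order(centers[, 1], centers[, 2], centers[, 3])
  best <- ord[which(means[ord] == max(means))[1]]
  structure(means[best], center = centers[best, ])
}

#' Segment lesions above a blood-pool-derived threshold
#'
#' Connected components (26-connectivity by default) of voxels with
#' SUV strictly greater than the threshold, excluding an optional mask of
#' physiological uptake (e.g., the aortic VOI region). Components smaller
#' than `min_volume_ml` (0.3 mL by default) are disregarded, and each
#' surviving component must additionally have `suv_peak > threshold`.
#' Components are labeled deterministically by decreasing volume (ties by
#' smallest linear voxel index).
#'
#' @param volume an [suv_volume].
#' @param threshold SUV threshold (>= 0); voxels must exceed it strictly.
#' @param min_volume_ml minimum component volume in mL.
#' @param exclusion_mask optional logical array of voxels to exclude.
#' @param connectivity 26 (vertex), 18 (edge) or 6 (face) neighborhood.
#' @param sphere_diameter_mm SUVpeak sphere diameter for the peak check.
#' @param enforce_peak require `suv_peak(component) > threshold`.
#' @return a `segmentation` list: `labels` (integer array), `table`
#'   (lesion_id, n_voxels, volume_ml), `threshold`, `n_dropped_small`,
#'   `n_dropped_peak`.
#' @export
segment_lesions <- function(volume, threshold, min_volume_ml = 0.3,
                            exclusion_mask = NULL, connectivity = 26,
                            sphere_diameter_mm = 12, enforce_peak = TRUE) {
  stopifnot(inherits(volume, "suv_volume"))
  if (!is_scalar_num(threshold) || threshold < 0)
    abort("threshold must be a non-negative SUV")
  d <- dim(volume$values)
  vox_ml <- voxel_volume_ml(volume)
  mask <- volume$values > threshold
  if (!is.null(exclusion_mask)) mask <- mask & !exclusion_mask
  empty <- list(labels = array(0L, d),
                table = data.frame(lesion_id = integer(), n_voxels = integer(),
                                   volume_ml = numeric()),
                threshold = threshold, n_dropped_small = 0L, n_dropped_peak = 0L)
  class(empty) <- "segmentation"
  idx <- which(mask)
  if (length(idx) == 0) return(empty)

  membership <- label_components(mask, connectivity)
  comp_ids <- seq_len(max(membership))
  sizes <- tabulate(membership, nbins = length(comp_ids))
  vols <- sizes * vox_ml

  keep <- which(vols >= min_volume_ml)
  n_small <- length(comp_ids) - length(keep)
  n_peak <- 0L
  if (enforce_peak && length(keep)) {
    ok <- vapply(keep, function(k) {
      comp_idx <- idx[membership == k]
      as.numeric(suv_peak(volume, comp_idx, sphere_diameter_mm)) > threshold
    }, TRUE)
    n_peak <- sum(!ok)
    keep <- keep[ok]
  }
  if (!length(keep)) {
    empty$n_dropped_small <- n_small
    empty$n_dropped_peak <- n_peak
    return(empty)
  }
  ## deterministic labels: decreasing volume, ties by first voxel index
  first_idx <- vapply(keep, function(k) min(idx[membership == k]), 0L)
  ord <- keep[order(-vols[keep], first_idx)]
  labels <- array(0L, d)
  for (new_id in seq_along(ord))
    labels[idx[membership == ord[new_id]]] <- new_id
  out <- list(labels = labels,
              table = data.frame(lesion_id = seq_along(ord),
                                 n_voxels = sizes[ord],
                                 volume_ml = vols[ord]),
              threshold = threshold,
              n_dropped_small = n_small, n_dropped_peak = n_peak)
  class(out) <- "segmentation"
  out
}

## connected-component labeling over the voxel adjacency graph
label_components <- function(mask, connectivity = 26) {
  d <- dim(mask)
  idx <- which(mask)
  nv <- length(idx)
  off <- neighbor_offsets(connectivity)
  id_map <- array(0L, d)
  id_map[idx] <- seq_len(nv)
  co <- arrayInd(idx, d)
  edges <- vector("list", nrow(off))
  for (j in seq_len(nrow(off))) {
    zz <- co[, 1] + off[j, 1]; yy <- co[, 2] + off[j, 2]
    xx <- co[, 3] + off[j, 3]
    ok <- zz >= 1 & zz <= d[1] & yy >= 1 & yy <= d[2] & xx >= 1 & xx <= d[3]
    if (!any(ok)) next
    nbr <- id_map[cbind(zz[ok], yy[ok], xx[ok])]
    hit <- nbr > 0L
    if (any(hit))
      edges[[j]] <- rbind(which(ok)[hit], nbr[hit])
  }
  em <- do.call(cbind, edges)
  g <- igraph::make_empty_graph(n = nv, directed = FALSE)
  if (!is.null(em)) g <- igraph::add_edges(g, as.vector(em))
  igraph::components(g)$membership
}

## half-neighborhood (lexicographically positive) offsets
neighbor_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  g <- switch(as.character(connectivity),
              "6" = g[rowSums(abs(g)) == 1, , drop = FALSE],
              "18" = g[rowSums(abs(g)) <= 2, , drop = FALSE],
              "26" = g,
              abort("connectivity must be 6, 18 or 26"))
  ## keep one of each +/- pair
  key <- g[, 1] * 9 + g[, 2] * 3 + g[, 3]
  g[key > 0, , drop = FALSE]
}

#' Quantify a single scan
#'
#' Runs the full single-scan chain: aortic blood-pool statistics, the
#' PERCIST-style threshold `1.5 * peak + 2 * SD`, lesion segmentation with
#' the 0.3 mL filter (the aortic VOI region is excluded as physiological
#' uptake), and per-lesion metrics. Patient-level burden metrics are
#' `PSMA-TV = sum of lesion volumes` (mL) and
#' `TL-PSMA = sum over lesions of SUVpeak * volume` (SUV*cm^3); the
#' alternative global reading `TL-PSMA = global SUVpeak * PSMA-TV` is
#' available via `tl_psma_mode = "global"`.
#'
#' @param volume an [suv_volume].
#' @param aorta_center cylinder VOI center in mm, (z, y, x).
#' @param aorta list of cylinder overrides: `axis`, `diameter`, `length`.
#' @param site_labels optional integer label volume assigning voxels to
#'   sites; each lesion gets the majority site among its voxels
#'   (`"unknown"` when unlabeled).
#' @param site_names site name per positive label value in `site_labels`.
#' @param min_volume_ml,sphere_diameter_mm,connectivity segmentation
#'   parameters, see [segment_lesions].
#' @param exclusion_mask extra exclusion mask (added to the aortic VOI).
#' @param tl_psma_mode `"per_lesion"` (default) or `"global"`.
#' @return a `scan_quant` list: `threshold`, `aorta` ([aorta_stats]),
#'   `lesions` (data.frame with lesion_id, site, n_voxels, volume_ml,
#'   suv_peak, suv_max, centroid_z/y/x), `psma_tv_ml`, `tl_psma`,
#'   `labels` (segmentation label volume), `n_dropped_small`.
#' @export
quantify_scan <- function(volume, aorta_center, aorta = list(),
                          site_labels = NULL, site_names = NULL,
                          min_volume_ml = 0.3, sphere_diameter_mm = 12,
                          connectivity = 26, exclusion_mask = NULL,
                          tl_psma_mode = c("per_lesion", "global")) {
  tl_psma_mode <- match.arg(tl_psma_mode)
  ao <- utils::modifyList(list(axis = "z", diameter = 10, length = 30), aorta)
  ast <- aorta_stats(volume, aorta_center, ao$axis, ao$diameter, ao$length,
                     sphere_diameter_mm)
  thr <- compute_threshold(ast)
  excl <- ast$mask
  if (!is.null(exclusion_mask)) excl <- excl | exclusion_mask
  seg <- segment_lesions(volume, thr, min_volume_ml, excl, connectivity,
                         sphere_diameter_mm)
  les <- seg$table
  n <- nrow(les)
  d <- dim(volume$values)
  if (n > 0) {
    per <- lapply(seq_len(n), function(k) {
      comp_idx <- which(seg$labels == k)
      pk <- suv_peak(volume, comp_idx, sphere_diameter_mm)
      ctr <- colMeans(voxel_centers_mm(arrayInd(comp_idx, d), volume$spacing))
      site <- "unknown"
      if (!is.null(site_labels)) {
        lab <- site_labels[comp_idx]
        lab <- lab[lab > 0]
        if (length(lab)) {
          tab <- sort(table(lab), decreasing = TRUE)
          maj <- as.integer(names(tab)[1])
          site <- if (!is.null(site_names) && maj <= length(site_names))
            site_names[maj] else as.character(maj)
        }
      }
      list(suv_peak = as.numeric(pk),
           suv_max = max(volume$values[comp_idx]),
           centroid = ctr, site = site)
    })
    les$site <- vapply(per, `[[`, "", "site")
    les$suv_peak <- vapply(per, `[[`, 0, "suv_peak")
    les$suv_max <- vapply(per, `[[`, 0, "suv_max")
    ctr <- t(vapply(per, `[[`, numeric(3), "centroid"))
    les$centroid_z <- ctr[, 1]; les$centroid_y <- ctr[, 2]
    les$centroid_x <- ctr[, 3]
  } else {
    les$site <- character(0); les$suv_peak <- numeric(0)
    les$suv_max <- numeric(0)
    les$centroid_z <- les$centroid_y <- les$centroid_x <- numeric(0)
  }
  psma_tv <- sum(les$volume_ml)
  tl_psma <- if (n == 0) 0
  else if (tl_psma_mode == "per_lesion") sum(les$suv_peak * les$volume_ml)
  else max(les$suv_peak) * psma_tv
  structure(list(threshold = thr, aorta = ast, lesions = les,
                 psma_tv_ml = psma_tv, tl_psma = tl_psma,
                 labels = seg$labels,
                 n_dropped_small = seg$n_dropped_small,
                 tl_psma_mode = tl_psma_mode),
            class = "scan_quant")
}

#' @export
print.scan_quant <- function(x, ...) {
  cat(sprintf("Scan quantification: threshold %.3f SUV, %d lesion(s)\n",
              x$threshold, nrow(x$lesions)))
  cat(sprintf("  PSMA-TV %.2f mL, TL-PSMA %.2f SUV*cm^3 (%s)\n",
              x$psma_tv_ml, x$tl_psma, x$tl_psma_mode))
  if (x$n_dropped_small > 0)
    cat(sprintf("  %d segment(s) below the 0.3 mL filter were disregarded\n",
                x$n_dropped_small))
  invisible(x)
}

#' Select the most- and least-avid lesions per organ category
#'
#' For each metastasis category (lymph node, bone, visceral) the `k`
#' highest- and `k` lowest-SUVpeak lesions are kept (all lesions when the
#' category holds at most `2k`), plus the most avid primary prostate
#' lesion when present. Ties are broken by lesion id.
#'
#' @param scan a `scan_quant` or a lesion data.frame with columns `site`,
#'   `suv_peak`, `lesion_id`.
#' @param k lesions to keep at each extreme per category (default 2).
#' @return the selected subset of the lesion table.
#' @export
select_extreme_lesions <- function(scan, k = 2) {
  les <- if (inherits(scan, "scan_quant")) scan$lesions else scan
  stopifnot(all(c("site", "suv_peak", "lesion_id") %in% names(les)))
  picked <- lapply(c("lymph_node", "bone", "visceral"), function(s) {
    sub <- les[les$site == s, , drop = FALSE]
    if (nrow(sub) <= 2 * k) return(sub)
    ord <- sub[order(sub$suv_peak, sub$lesion_id), , drop = FALSE]
    rbind(utils::head(ord, k), utils::tail(ord, k))
  })
  pros <- les[les$site == "prostate", , drop = FALSE]
  if (nrow(pros) > 0) {
    ord <- pros[order(-pros$suv_peak, pros$lesion_id), , drop = FALSE]
    picked <- c(picked, list(ord[1, , drop = FALSE]))
  }
  out <- do.call(rbind, picked)
  out[order(out$site, out$lesion_id), , drop = FALSE]
}
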