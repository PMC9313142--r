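## Response classification. Imaging categories follow PERCIST-style +/-30%
## SUVpeak (lesion) / TL-PSMA (patient) rules with inclusive boundaries;
## biochemical categories follow the PCWG PSA rules (>50% reduction = bPR,
## >=25% increase = bPD). A small numeric tolerance absorbs floating-point
## error exactly at the boundaries.

.pct_eps <- 1e-9

#' Percent change
#'
#' `100 * (post - pre) / pre`; the baseline must be positive.
#'
#' @param pre baseline value(s), > 0.
#' @param post follow-up value(s).
#' @return percent change (full precision; reports round to 2 decimals).
#' @examples
#' percent_change(1961.02, 97.79)   # -95.01
#' percent_change(260.58, 2216.94)  # +750.77
#' @export
percent_change <- function(pre, post) {
  if (any(!is.finite(pre)) || any(pre <= 0))
    abort("baseline value must be positive")
  100 * (post - pre) / pre
}

#' Classify lesion-level imaging response
#'
#' A lesion whose follow-up SUVpeak fell below the segmentation threshold
#' is recorded as 0 and classified iCR (complete resolution of tracer
#' accumulation). Otherwise: change <= -30% is iPR, change >= +30% is iPD
#' (boundaries inclusive), anything else iSD. Objective response is
#' iCR or iPR. New lesions are not classified at the lesion level
#' (baseline 0 is an error).
#'
#' @param suv_peak_baseline baseline SUVpeak (> 0), vectorized.
#' @param suv_peak_followup follow-up SUVpeak (0 if resolved).
#' @param pct response/progression boundary in percent (default 30).
#' @return factor with levels iCR, iPR, iSD, iPD.
#' @export
classify_lesion <- function(suv_peak_baseline, suv_peak_followup, pct = 30) {
  if (any(!is.finite(suv_peak_baseline)) || any(suv_peak_baseline <= 0))
    abort("baseline SUVpeak must be positive (new lesions are not classified)")
  if (any(suv_peak_followup < 0)) abort("follow-up SUVpeak must be >= 0")
  ch <- percent_change(suv_peak_baseline, suv_peak_followup)
  out <- ifelse(suv_peak_followup == 0, "iCR",
         ifelse(ch <= -pct + .pct_eps, "iPR",
         ifelse(ch >= pct - .pct_eps, "iPD", "iSD")))
  factor(out, levels = c("iCR", "iPR", "iSD", "iPD"))
}

#' Classify patient-level imaging response
#'
#' Uses TL-PSMA as the distinctive parameter: a reduction of >= 30% is
#' objective response (iPR); an increase of >= 30% and/or the appearance
#' of new lesions is iPD (new lesions take precedence over any TL-PSMA
#' decrease); anything else is iSD. Patient-level complete response is
#' not emitted as a separate category; complete resolution of all disease
#' (TL-PSMA falling to 0, a -100% change) is reported as iPR.
#'
#' @param tl_psma_pre baseline TL-PSMA (> 0), vectorized.
#' @param tl_psma_post follow-up TL-PSMA.
#' @param any_new_lesion logical flag(s).
#' @param pct response/progression boundary in percent (default 30).
#' @return factor with levels iPR, iSD, iPD.
#' @examples
#' classify_patient(1961.02, 97.79, FALSE)   # iPR (responder)
#' classify_patient(260.58, 2216.94, FALSE)  # iPD
#' @export
classify_patient <- function(tl_psma_pre, tl_psma_post,
                             any_new_lesion = FALSE, pct = 30) {
  if (any(!is.finite(tl_psma_pre)) || any(tl_psma_pre <= 0))
    abort("baseline TL-PSMA must be positive")
  ch <- percent_change(tl_psma_pre, tl_psma_post)
  out <- ifelse(any_new_lesion, "iPD",
         ifelse(ch <= -pct + .pct_eps, "iPR",
         ifelse(ch >= pct - .pct_eps, "iPD", "iSD")))
  factor(out, levels = c("iPR", "iSD", "iPD"))
}

#' Classify biochemical (PSA) response
#'
#' PCWG-style rules: more than 50% PSA reduction is bPR; an increase of
#' >= 25% is bPD; a reduction of at most 50% together with an increase
#' below 25% is bSD. Note the asymmetric boundaries: exactly -50% is bSD,
#' exactly +25% is bPD.
#'
#' @param psa_pre baseline PSA in ng/mL (> 0), vectorized.
#' @param psa_post follow-up PSA.
#' @param reduction_pct bPR boundary (strict reduction, default 50).
#' @param increase_pct bPD boundary (inclusive increase, default 25).
#' @return factor with levels bPR, bSD, bPD.
#' @export
classify_biochemical <- function(psa_pre, psa_post,
                                 reduction_pct = 50, increase_pct = 25) {
  if (any(!is.finite(psa_pre)) || any(psa_pre <= 0))
    abort("baseline PSA must be positive")
  ch <- percent_change(psa_pre, psa_post)
  out <- ifelse(ch < -reduction_pct - .pct_eps, "bPR",
         ifelse(ch >= increase_pct - .pct_eps, "bPD", "bSD"))
  factor(out, levels = c("bPR", "bSD", "bPD"))
}

#' Match lesions between baseline and follow-up scans
#'
#' With an explicit `id_map` (named vector, baseline lesion id ->
#' follow-up lesion id) the mapping is used directly. Otherwise matching
#' is greedy nearest-centroid: candidate pairs within `max_dist_mm`
#' (same site when `same_site` and both sites are known) are accepted in
#' order of increasing centroid distance. Unmatched baseline lesions get
#' follow-up SUVpeak 0 (resolved below threshold); unmatched follow-up
#' lesions are flagged as new.
#'
#' @param baseline,followup `scan_quant` objects or lesion data.frames
#'   with columns lesion_id, site, suv_peak, centroid_z/y/x.
#' @param id_map optional named integer vector mapping baseline to
#'   follow-up lesion ids; duplicated entries on either side are an error.
#' @param max_dist_mm maximum centroid distance for a match (default 15).
#' @param same_site require matched lesions to share a site category.
#' @return data.frame of lesion pairs: lesion_id (baseline; NA for new
#'   lesions), followup_id, site, suv_peak_baseline, suv_peak_followup,
#'   distance_mm, matched, new_lesion.
#' @export
match_lesions <- function(baseline, followup, id_map = NULL,
                          max_dist_mm = 15, same_site = TRUE) {
  b <- if (inherits(baseline, "scan_quant")) baseline$lesions else baseline
  f <- if (inherits(followup, "scan_quant")) followup$lesions else followup

  pairs <- data.frame(lesion_id = b$lesion_id, followup_id = NA_integer_,
                      site = if (nrow(b)) b$site else character(0),
                      suv_peak_baseline = b$suv_peak,
                      suv_peak_followup = 0,
                      distance_mm = NA_real_,
                      matched = FALSE, new_lesion = FALSE)
  used_f <- logical(nrow(f))

  if (!is.null(id_map)) {
    ids_b <- as.integer(names(id_map))
    if (anyDuplicated(ids_b) || anyDuplicated(id_map))
      abort("duplicate ids in id_map")
    for (i in seq_along(id_map)) {
      bi <- match(ids_b[i], b$lesion_id)
      fi <- match(as.integer(id_map[i]), f$lesion_id)
      if (is.na(bi) || is.na(fi)) abort("id_map refers to unknown lesion ids")
      pairs$followup_id[bi] <- f$lesion_id[fi]
      pairs$suv_peak_followup[bi] <- f$suv_peak[fi]
      pairs$matched[bi] <- TRUE
      used_f[fi] <- TRUE
    }
  } else if (nrow(b) > 0 && nrow(f) > 0) {
    bc <- as.matrix(b[, c("centroid_z", "centroid_y", "centroid_x")])
    fc <- as.matrix(f[, c("centroid_z", "centroid_y", "centroid_x")])
    dmat <- outer(rowSums(bc^2), rep(1, nrow(f))) +
            outer(rep(1, nrow(b)), rowSums(fc^2)) - 2 * bc %*% t(fc)
    dmat <- sqrt(pmax(dmat, 0))
    cand <- which(dmat <= max_dist_mm, arr.ind = TRUE)
    if (same_site && nrow(cand)) {
      sb <- b$site[cand[, 1]]; sf <- f$site[cand[, 2]]
      ok <- sb == sf | sb == "unknown" | sf == "unknown"
      cand <- cand[ok, , drop = FALSE]
    }
    if (nrow(cand)) {
      cand <- cand[order(dmat[cand]), , drop = FALSE]
      used_b <- logical(nrow(b))
      for (r in seq_len(nrow(cand))) {
        bi <- cand[r, 1]; fi <- cand[r, 2]
        if (used_b[bi] || used_f[fi]) next
        used_b[bi] <- TRUE; used_f[fi] <- TRUE
        pairs$followup_id[bi] <- f$lesion_id[fi]
        pairs$suv_peak_followup[bi] <- f$suv_peak[fi]
        pairs$distance_mm[bi] <- dmat[bi, fi]
        pairs$matched[bi] <- TRUE
      }
    }
  }
  if (any(!used_f)) {
    new <- data.frame(lesion_id = NA_integer_,
                      followup_id = f$lesion_id[!used_f],
                      site = f$site[!used_f],
                      suv_peak_baseline = NA_real_,
                      suv_peak_followup = f$suv_peak[!used_f],
                      distance_mm = NA_real_,
                      matched = FALSE, new_lesion = TRUE)
    pairs <- rbind(pairs, new)
  }
  rownames(pairs) <- NULL
  pairs
}
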