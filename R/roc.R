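## Empirical ROC analysis for baseline-avidity response prediction.
## Convention: higher score => predicted responder; a cutoff c predicts
## positive when score >= c. Candidate cutoffs are the observed scores
## plus +Inf (the all-negative rule), so every achievable confusion
## matrix is visited.

roc_points <- function(scores, labels) {
  labels <- as.logical(labels)
  thr <- c(sort(unique(scores)), Inf)
  npos <- sum(labels); nneg <- sum(!labels)
  sens <- vapply(thr, function(c) sum(scores[labels] >= c), 0) / npos
  spec <- vapply(thr, function(c) sum(scores[!labels] < c), 0) / nneg
  data.frame(cutoff = thr, sens = sens, spec = spec)
}

trapezoid_auc <- function(fpr, tpr) {
  ord <- order(fpr, tpr)
  fpr <- c(fpr[ord]); tpr <- c(tpr[ord])
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

## fast AUC (Mann-Whitney with 0.5 for ties); used inside the bootstrap
auc_mw <- function(scores, labels) {
  labels <- as.logical(labels)
  r <- rank(scores)
  npos <- sum(labels); nneg <- sum(!labels)
  (sum(r[labels]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' ROC analysis with Youden and minimum-specificity cutoffs
#'
#' Builds the empirical ROC of a continuous score (e.g., baseline lesion
#' SUVpeak) against a binary response label, higher score predicting
#' response. Two operating points are reported: the Youden cutoff
#' maximizing `sensitivity + specificity - 1` (ties resolved toward
#' higher specificity, then the larger cutoff, favoring the
#' high-specificity use of the rule-out cutoff) and the smallest cutoff
#' achieving at least `min_spec` specificity (0.80 by default), with its
#' sensitivity. AUC is computed by the trapezoid rule.
#'
#' @param scores numeric predictor values.
#' @param responder logical (or 0/1) response labels; both classes must be
#'   present.
#' @param min_spec minimum specificity for the second cutoff.
#' @return a `roc_result`: `auc`, `curve` (cutoff/sens/spec table),
#'   `cutoff_youden`, `sens_youden`, `spec_youden`, `youden_j`,
#'   `cutoff_minspec`, `sens_minspec`, `spec_minspec`, `n_pos`, `n_neg`.
#' @export
roc_cutoffs <- function(scores, responder, min_spec = 0.80) {
  responder <- as.logical(responder)
  ok <- is.finite(scores) & !is.na(responder)
  scores <- scores[ok]; responder <- responder[ok]
  if (length(unique(responder)) < 2)
    abort("both responder classes must be present")
  pts <- roc_points(scores, responder)
  auc <- trapezoid_auc(1 - pts$spec, pts$sens)

  ## ties in J (and in specificity among tied J) are detected with a small
  ## numeric tolerance: operating points that are mathematically tied can
  ## differ in the last floating-point digit
  j <- pts$sens + pts$spec - 1
  best <- which(j > max(j) - 1e-12)
  best <- best[pts$spec[best] > max(pts$spec[best]) - 1e-12]
  best <- best[which.max(pts$cutoff[best])]

  elig <- which(pts$spec >= min_spec)
  ms <- elig[which.min(pts$cutoff[elig])]

  structure(list(auc = auc, curve = pts,
                 cutoff_youden = pts$cutoff[best],
                 sens_youden = pts$sens[best],
                 spec_youden = pts$spec[best],
                 youden_j = j[best],
                 cutoff_minspec = pts$cutoff[ms],
                 sens_minspec = pts$sens[ms],
                 spec_minspec = pts$spec[ms],
                 min_spec = min_spec,
                 n_pos = sum(responder), n_neg = sum(!responder)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC %.3f (%d responders / %d non-responders)\n",
              x$auc, x$n_pos, x$n_neg))
  cat(sprintf("  Youden cutoff %.2f: sens %.2f, spec %.2f\n",
              x$cutoff_youden, x$sens_youden, x$spec_youden))
  cat(sprintf("  min-spec (>= %.2f) cutoff %.2f: sens %.2f, spec %.2f\n",
              x$min_spec, x$cutoff_minspec, x$sens_minspec, x$spec_minspec))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  graphics::plot(1 - x$curve$spec, x$curve$sens, type = "s",
                 xlab = "1 - specificity", ylab = "Sensitivity",
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3, col = "grey")
  graphics::points(1 - x$spec_youden, x$sens_youden, pch = 19)
  graphics::legend("bottomright", bty = "n",
                   legend = sprintf("AUC = %.3f", x$auc))
  invisible(x)
}

#' Bootstrap optimism-corrected AUC (c-statistic)
#'
#' Harrell's optimism correction for the apparent c-statistic of a
#' univariate logistic model (response ~ score): the apparent AUC minus
#' the mean, over `B` bootstrap resamples, of the difference between the
#' resample-fit model's AUC on the resample and its AUC on the original
#' data. Resamples with a single response class are redrawn (the number
#' of redraws is capped).
#'
#' @param scores numeric predictor.
#' @param responder logical response labels.
#' @param B number of bootstrap resamples (default 1000).
#' @param seed optional RNG seed.
#' @param max_redraws cap on degenerate-resample redraws.
#' @return list with `auc_corrected`, `auc_apparent`, `optimism`, `B`.
#' @export
bootstrap_corrected_auc <- function(scores, responder, B = 1000,
                                    seed = NULL, max_redraws = 10 * B) {
  responder <- as.logical(responder)
  if (B < 1) abort("B must be >= 1")
  if (length(unique(responder)) < 2)
    abort("both responder classes must be present")
  if (!is.null(seed)) set.seed(seed)
  n <- length(scores)
  fit0 <- suppressWarnings(stats::glm(responder ~ scores,
                                      family = stats::binomial()))
  apparent <- auc_mw(stats::fitted(fit0), responder)
  optimism <- numeric(B)
  redraws <- 0L
  b <- 1L
  while (b <= B) {
    idx <- sample.int(n, n, replace = TRUE)
    if (length(unique(responder[idx])) < 2) {
      redraws <- redraws + 1L
      if (redraws > max_redraws)
        abort("too many degenerate bootstrap resamples")
      next
    }
    df_b <- data.frame(y = responder[idx], s = scores[idx])
    fit_b <- suppressWarnings(stats::glm(y ~ s, family = stats::binomial(),
                                         data = df_b))
    auc_b <- auc_mw(stats::fitted(fit_b), df_b$y)
    pred_orig <- stats::predict(fit_b,
                                newdata = data.frame(s = scores),
                                type = "response")
    auc_orig <- auc_mw(pred_orig, responder)
    optimism[b] <- auc_b - auc_orig
    b <- b + 1L
  }
  list(auc_corrected = apparent - mean(optimism),
       auc_apparent = apparent, optimism = mean(optimism), B = B)
}
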