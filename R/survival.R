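#' Kaplan-Meier curves with log-rank comparison
#'
#' Product-limit survival estimate per group (overall when `groups` is
#' `NULL`), group medians (first time the survival curve drops to 0.5 or
#' below; `NA` when not reached, e.g., an all-censored group) and the
#' two-sided log-rank test across groups.
#'
#' @param times follow-up times (months), >= 0.
#' @param events event indicators (1 = death, 0 = censored).
#' @param groups optional grouping factor (>= 2 groups for the log-rank
#'   test).
#' @return a `survival_result`: `curves` (group, time, n_risk, n_event,
#'   surv), `medians` (per group, months), `logrank_p`, `logrank_chisq`,
#'   and the `survfit` object.
#' @export
km_logrank <- function(times, events, groups = NULL) {
  if (any(times < 0)) abort("survival times must be >= 0")
  events <- as.integer(events)
  dat <- data.frame(time = times, event = events)
  if (is.null(groups)) {
    fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = dat)
    grp_names <- "all"
    logrank_p <- logrank_chisq <- NA_real_
  } else {
    dat$group <- factor(groups)
    if (nlevels(dat$group) < 2) abort("log-rank needs >= 2 groups")
    fit <- survival::survfit(survival::Surv(time, event) ~ group, data = dat)
    grp_names <- sub("^group=", "", names(fit$strata))
    sd_ <- survival::survdiff(survival::Surv(time, event) ~ group, data = dat)
    logrank_chisq <- sd_$chisq
    logrank_p <- stats::pchisq(sd_$chisq, df = length(sd_$n) - 1,
                               lower.tail = FALSE)
  }
  s <- summary(fit, censored = TRUE)
  grp <- if (is.null(fit$strata)) rep("all", length(s$time))
         else sub("^group=", "", as.character(s$strata))
  curves <- data.frame(group = grp, time = s$time, n_risk = s$n.risk,
                       n_event = s$n.event, surv = s$surv,
                       stringsAsFactors = FALSE)
  medians <- vapply(grp_names, function(g) {
    cg <- curves[curves$group == g, ]
    hit <- which(cg$surv <= 0.5)
    if (length(hit)) cg$time[min(hit)] else NA_real_
  }, 0)
  structure(list(curves = curves, medians = medians,
                 logrank_p = logrank_p, logrank_chisq = logrank_chisq,
                 fit = fit),
            class = "survival_result")
}

#' @export
print.survival_result <- function(x, ...) {
  cat("Kaplan-Meier survival\n")
  for (g in names(x$medians))
    cat(sprintf("  %s: median OS %s months\n", g,
                if (is.na(x$medians[g])) "not reached"
                else format(x$medians[g])))
  if (is.finite(x$logrank_p))
    cat(sprintf("  log-rank: chi^2 %.3f, p = %.3g\n",
                x$logrank_chisq, x$logrank_p))
  invisible(x)
}

#' @export
plot.survival_result <- function(x, ...) {
  graphics::plot(x$fit, xlab = "Months since first cycle",
                 ylab = "Survival probability", ...)
  invisible(x)
}

#' Univariate Cox proportional-hazards screen
#'
#' Partial-likelihood fit with Efron tie handling of a single covariate
#' (numeric, logical, or a factor expanded to reference-coded contrasts,
#' reference = first level). Hazard ratios carry Wald intervals and
#' p-values; the overall covariate is tested by a likelihood-ratio test.
#' Monotone partial likelihood (e.g., a level with no events) is flagged
#' rather than silently reported.
#'
#' @param times follow-up times (months).
#' @param events event indicators (1 = event, 0 = censored); at least one
#'   event is required.
#' @param covariate the tested covariate (vector, same length).
#' @param name label for the covariate in the output.
#' @param conf confidence level.
#' @return a `cox_result`: `hr_table` (term, estimate (log HR), se, hr,
#'   hr_ci_lo, hr_ci_hi, p_wald; reference levels appear with hr = 1),
#'   `lrt_p`, `monotone` flag, `n`, `n_events`, the `coxph` `fit`.
#' @export
cox_univariate <- function(times, events, covariate, name = "covariate",
                           conf = 0.95) {
  events <- as.integer(events)
  if (sum(events) < 1) abort("at least one event is required")
  dat <- data.frame(time = times, event = events, x = covariate)
  monotone <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ x, data = dat,
                    ties = "efron"),
    warning = function(cond) {
      if (grepl("infinite|did not converge|beta may be", conditionMessage(cond)))
        monotone <<- TRUE
      invokeRestart("muffleWarning")
    })
  sm <- summary(fit)
  cf <- sm$coefficients
  zq <- stats::qnorm(1 - (1 - conf) / 2)
  terms <- sub("^x", name, rownames(cf))
  hr_table <- data.frame(term = terms,
                         estimate = cf[, "coef"], se = cf[, "se(coef)"],
                         hr = exp(cf[, "coef"]),
                         hr_ci_lo = exp(cf[, "coef"] - zq * cf[, "se(coef)"]),
                         hr_ci_hi = exp(cf[, "coef"] + zq * cf[, "se(coef)"]),
                         p_wald = cf[, "Pr(>|z|)"],
                         row.names = NULL, stringsAsFactors = FALSE)
  if (is.factor(covariate))
    hr_table <- rbind(data.frame(term = paste0(name, levels(covariate)[1],
                                               " (ref)"),
                                 estimate = 0, se = NA_real_, hr = 1,
                                 hr_ci_lo = NA_real_, hr_ci_hi = NA_real_,
                                 p_wald = NA_real_,
                                 stringsAsFactors = FALSE),
                      hr_table)
  structure(list(hr_table = hr_table,
                 lrt_p = sm$logtest["pvalue"][[1]],
                 loglik = fit$loglik,
                 monotone = monotone, n = nrow(dat), n_events = sum(events),
                 fit = fit),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("Cox PH (Efron ties): %d subjects, %d events\n",
              x$n, x$n_events))
  ht <- x$hr_table
  for (i in seq_len(nrow(ht))) {
    if (is.na(ht$se[i]))
      cat(sprintf("  %s: HR 1 (reference)\n", ht$term[i]))
    else
      cat(sprintf("  %s: HR %.3g (%.3g-%.3g), p = %.3g\n", ht$term[i],
                  ht$hr[i], ht$hr_ci_lo[i], ht$hr_ci_hi[i], ht$p_wald[i]))
  }
  cat(sprintf("  overall LRT p = %.3g%s\n", x$lrt_p,
              if (x$monotone) " [monotone likelihood flagged]" else ""))
  invisible(x)
}
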