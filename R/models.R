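#' Accumulation-response linear mixed model
#'
#' Fits, by maximum likelihood, a linear mixed model of log baseline
#' uptake (log SUVpeak or log SUVmax) on the imaging response, with a
#' random intercept per patient absorbing between-patient variation in
#' uptake level. The response enters either dichotomized
#' (responder = iCR or iPR) or as a categorical variable with iPD as the
#' reference level; baseline PSMA-TV and metastasis site can be added as
#' confounders and site optionally as an interaction with response. ML
#' (not REML) is used throughout so the likelihood-ratio test against the
#' model without the response terms is valid. Because the outcome is
#' log-transformed, exponentiated coefficients are the multiplicative
#' difference in uptake between a category and its reference (e.g., 1.80
#' means responding lesions show 1.8-fold higher SUVpeak).
#'
#' @param rows lesion-level data.frame with columns `patient_id`, the
#'   chosen outcome, and the requested response/covariate columns
#'   (`responder` logical or `response` factor with levels iPD, iSD, iPR,
#'   iCR; optionally `psma_tv`, `site`).
#' @param outcome `"log_suv_peak"` or `"log_suv_max"`.
#' @param response_term `"responder"` (dichotomous) or `"response"`
#'   (categorical, iPD reference).
#' @param covariates confounder columns added as fixed effects; defaults
#'   to those of `psma_tv` and `site` present in `rows`.
#' @param interaction add the site-by-response interaction.
#' @param lrt compute the likelihood-ratio test against the model without
#'   the response terms.
#' @param conf confidence level for Wald intervals.
#' @return a `mixed_model_result`: `coefficients` (term, estimate, se,
#'   ci_lo, ci_hi, exp_estimate, exp_ci_lo, exp_ci_hi, p_wald), `lrt_p`,
#'   `lrt_df`, `tau2` (random-intercept variance), `sigma2` (residual
#'   variance), `icc`, `n_patients`, `n_lesions`, and the `lme4` `fit`.
#' @export
fit_lmm <- function(rows, outcome = c("log_suv_peak", "log_suv_max"),
                    response_term = c("responder", "response"),
                    covariates = NULL, interaction = FALSE,
                    lrt = TRUE, conf = 0.95) {
  outcome <- match.arg(outcome)
  response_term <- match.arg(response_term)
  if (is.null(covariates))
    covariates <- intersect(c("psma_tv", "site"), names(rows))
  need <- c("patient_id", outcome, response_term, covariates)
  miss <- setdiff(need, names(rows))
  if (length(miss)) abort("missing columns: ", paste(miss, collapse = ", "))
  if (length(unique(rows$patient_id)) < 2)
    abort("at least 2 patients are required for a random intercept")

  dat <- rows
  ## PSMA-TV enters per liter, the reporting convention for tumor volume;
  ## also keeps fixed-effect predictors on comparable scales
  if ("psma_tv" %in% covariates) {
    dat$psma_tv_l <- dat$psma_tv / 1000
    covariates[covariates == "psma_tv"] <- "psma_tv_l"
  }
  if (response_term == "responder") {
    dat$.resp <- factor(ifelse(as.logical(dat$responder),
                               "Responders", "Non-responders"),
                        levels = c("Non-responders", "Responders"))
  } else {
    dat$.resp <- factor(as.character(dat$response),
                        levels = c("iPD", "iSD", "iPR", "iCR"))
    dat$.resp <- droplevels(dat$.resp)
  }
  fixed <- c(".resp", covariates,
             if (interaction && "site" %in% covariates) ".resp:site")
  f_full <- stats::as.formula(paste(outcome, "~",
                                    paste(fixed, collapse = " + "),
                                    "+ (1 | patient_id)"))
  ## rank check on the fixed-effects design before fitting
  mm <- stats::model.matrix(
    stats::as.formula(paste(outcome, "~", paste(fixed, collapse = " + "))),
    data = dat)
  qrm <- qr(mm)
  if (qrm$rank < ncol(mm)) {
    bad <- colnames(mm)[qrm$pivot[(qrm$rank + 1):ncol(mm)]]
    abort("singular fixed-effects design; collinear terms: ",
          paste(bad, collapse = ", "))
  }
  fit <- suppressMessages(lme4::lmer(f_full, data = dat, REML = FALSE))
  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  zq <- stats::qnorm(1 - (1 - conf) / 2)
  coefs <- data.frame(term = names(est), estimate = unname(est),
                      se = unname(se),
                      ci_lo = unname(est - zq * se),
                      ci_hi = unname(est + zq * se),
                      stringsAsFactors = FALSE)
  coefs$exp_estimate <- exp(coefs$estimate)
  coefs$exp_ci_lo <- exp(coefs$ci_lo)
  coefs$exp_ci_hi <- exp(coefs$ci_hi)
  coefs$p_wald <- 2 * stats::pnorm(-abs(coefs$estimate / coefs$se))

  vc <- as.data.frame(lme4::VarCorr(fit))
  tau2 <- vc$vcov[vc$grp == "patient_id"]
  sigma2 <- vc$vcov[vc$grp == "Residual"]

  lrt_p <- lrt_df <- NA_real_
  if (lrt) {
    f_null <- if (length(covariates))
      stats::as.formula(paste(outcome, "~", paste(covariates, collapse = " + "),
                              "+ (1 | patient_id)"))
    else stats::as.formula(paste(outcome, "~ 1 + (1 | patient_id)"))
    fit0 <- suppressMessages(lme4::lmer(f_null, data = dat, REML = FALSE))
    ll1 <- as.numeric(stats::logLik(fit))
    ll0 <- as.numeric(stats::logLik(fit0))
    lrt_df <- attr(stats::logLik(fit), "df") - attr(stats::logLik(fit0), "df")
    lrt_p <- stats::pchisq(2 * (ll1 - ll0), df = lrt_df, lower.tail = FALSE)
  }
  structure(list(coefficients = coefs, lrt_p = lrt_p, lrt_df = lrt_df,
                 tau2 = tau2, sigma2 = sigma2,
                 icc = tau2 / (tau2 + sigma2),
                 outcome = outcome, response_term = response_term,
                 n_patients = length(unique(dat$patient_id)),
                 n_lesions = nrow(dat), fit = fit),
            class = "mixed_model_result")
}

#' @export
print.mixed_model_result <- function(x, digits = 2, ...) {
  cat(sprintf("Mixed model: %s ~ %s + (1 | patient), ML fit\n",
              x$outcome, x$response_term))
  cat(sprintf("  %d lesions in %d patients; tau^2 %.3f, sigma^2 %.3f (ICC %.2f)\n",
              x$n_lesions, x$n_patients, x$tau2, x$sigma2, x$icc))
  if (is.finite(x$lrt_p))
    cat(sprintf("  LRT vs model without response terms: p = %.3g (df %d)\n",
                x$lrt_p, x$lrt_df))
  co <- x$coefficients
  out <- data.frame(
    term = co$term,
    coefficient = sprintf("%.*f (%.*f-%.*f)", digits, co$estimate,
                          digits, co$ci_lo, digits, co$ci_hi),
    `exp(coeff)` = sprintf("%.*f (%.*f-%.*f)", digits, co$exp_estimate,
                           digits, co$exp_ci_lo, digits, co$exp_ci_hi),
    p = format.pval(co$p_wald, digits = 3, eps = 1e-3),
    check.names = FALSE)
  print(out, row.names = FALSE)
  invisible(x)
}

#' @export
coef.mixed_model_result <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' Exponentiated coefficients of a fitted model report
#'
#' Returns the ratio-scale coefficients, `exp(coefficients)`; identical to
#' the `exp_estimate` column stored in the report.
#'
#' @param object a `mixed_model_result`.
#' @return named numeric vector of exponentiated coefficients.
#' @export
exp_coef <- function(object) {
  stats::setNames(object$coefficients$exp_estimate,
                  object$coefficients$term)
}

#' Geometric means with confidence intervals by group
#'
#' `exp(mean(log x))` per group with a t-based CI on the log scale,
#' the summary used for per-category baseline uptake.
#'
#' @param values positive values (e.g., baseline SUVpeak).
#' @param groups grouping factor (e.g., response category).
#' @param conf confidence level.
#' @return data.frame: group, n, gm, ci_lo, ci_hi, degenerate (TRUE when
#'   n = 1 and no CI exists).
#' @export
geometric_means <- function(values, groups, conf = 0.95) {
  if (any(!is.finite(values)) || any(values <= 0))
    abort("geometric means require positive values")
  groups <- factor(groups)
  res <- lapply(levels(groups), function(g) {
    x <- log(values[groups == g])
    n <- length(x)
    if (n == 0) abort("empty group: ", g)
    if (n == 1)
      return(data.frame(group = g, n = 1L, gm = exp(x), ci_lo = NA_real_,
                        ci_hi = NA_real_, degenerate = TRUE))
    se <- stats::sd(x) / sqrt(n)
    tq <- stats::qt(1 - (1 - conf) / 2, df = n - 1)
    data.frame(group = g, n = n, gm = exp(mean(x)),
               ci_lo = exp(mean(x) - tq * se), ci_hi = exp(mean(x) + tq * se),
               degenerate = FALSE)
  })
  do.call(rbind, res)
}

#' Covariate-adjusted univariate logistic screen with LRT
#'
#' Fits `outcome ~ variable + covariate` by ML logistic regression and
#' tests the variable by a likelihood-ratio test against
#' `outcome ~ covariate` (chi-squared, df = number of added terms). The
#' covariate defaults to baseline PSMA-TV, correcting each screen for
#' tumor load. Odds ratios carry Wald intervals. Quasi-separation
#' (diverging coefficients / fitted probabilities at 0 or 1) is detected
#' and flagged; the LRT p-value is still reported since the likelihood
#' difference remains meaningful when a Wald interval is not.
#'
#' @param data patient-level data.frame.
#' @param variable name of the tested column.
#' @param covariate name of the adjustment column (default `"psma_tv"`);
#'   `NULL` for an unadjusted screen.
#' @param outcome name of the binary outcome column (logical or 0/1).
#' @param conf confidence level.
#' @return a `logistic_lrt_result`: `or_table` (term, estimate (log-odds),
#'   se, or, or_ci_lo, or_ci_hi, p_wald), `lrt_p`, `lrt_df`, `separation`,
#'   `n`, fitted `fit`.
#' @export
logistic_lrt <- function(data, variable, covariate = "psma_tv",
                         outcome = "responder", conf = 0.95) {
  need <- c(variable, covariate, outcome)
  miss <- setdiff(need, names(data))
  if (length(miss)) abort("missing columns: ", paste(miss, collapse = ", "))
  y <- data[[outcome]]
  if (is.factor(y)) y <- y == levels(y)[2]
  y <- as.logical(y)
  if (length(unique(y[!is.na(y)])) < 2)
    abort("outcome must have both classes")
  dat <- data
  dat$.y <- y
  rhs1 <- paste(c(variable, covariate), collapse = " + ")
  rhs0 <- if (is.null(covariate)) "1" else paste(covariate, collapse = " + ")
  w <- NULL
  fit1 <- withCallingHandlers(
    stats::glm(stats::as.formula(paste(".y ~", rhs1)), data = dat,
               family = stats::binomial()),
    warning = function(cond) {
      w <<- conditionMessage(cond)
      invokeRestart("muffleWarning")
    })
  fit0 <- suppressWarnings(
    stats::glm(stats::as.formula(paste(".y ~", rhs0)), data = dat,
               family = stats::binomial()))
  p1 <- stats::fitted(fit1)
  separation <- any(p1 < 1e-8 | p1 > 1 - 1e-8) ||
    any(abs(stats::coef(fit1)) > 15, na.rm = TRUE) ||
    (!is.null(w) && grepl("fitted probabilities", w))
  if (!fit1$converged && !separation)
    abort("logistic model did not converge")

  cf <- summary(fit1)$coefficients
  keep <- setdiff(rownames(cf), c("(Intercept)", covariate))
  zq <- stats::qnorm(1 - (1 - conf) / 2)
  or_table <- data.frame(term = keep,
                         estimate = cf[keep, 1], se = cf[keep, 2],
                         or = exp(cf[keep, 1]),
                         or_ci_lo = exp(cf[keep, 1] - zq * cf[keep, 2]),
                         or_ci_hi = exp(cf[keep, 1] + zq * cf[keep, 2]),
                         p_wald = cf[keep, 4],
                         row.names = NULL, stringsAsFactors = FALSE)
  lrt_df <- fit0$df.residual - fit1$df.residual
  lrt_stat <- 2 * (as.numeric(stats::logLik(fit1)) -
                   as.numeric(stats::logLik(fit0)))
  lrt_p <- stats::pchisq(lrt_stat, df = lrt_df, lower.tail = FALSE)
  structure(list(or_table = or_table, lrt_p = lrt_p, lrt_df = lrt_df,
                 lrt_stat = lrt_stat, separation = separation,
                 variable = variable, covariate = covariate,
                 n = sum(!is.na(y)), fit = fit1),
            class = "logistic_lrt_result")
}

#' @export
print.logistic_lrt_result <- function(x, ...) {
  cat(sprintf("Logistic screen: %s (adjusted for %s), n = %d\n",
              x$variable,
              if (is.null(x$covariate)) "nothing" else x$covariate, x$n))
  ot <- x$or_table
  for (i in seq_len(nrow(ot)))
    cat(sprintf("  %s: OR %.3g (%.3g-%.3g)\n", ot$term[i], ot$or[i],
                ot$or_ci_lo[i], ot$or_ci_hi[i]))
  cat(sprintf("  LRT p = %.3g (df %d)%s\n", x$lrt_p, x$lrt_df,
              if (x$separation) " [quasi-separation detected]" else ""))
  invisible(x)
}
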