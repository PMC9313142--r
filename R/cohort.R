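#' Cohort simulation specification
#'
#' Parameters of the generative model mirrored by the inferential layer:
#' per-lesion log baseline SUVpeak is a site-specific mean plus a
#' per-patient random intercept (SD `tau`), a responder contrast
#' (`responder_log_ratio`, default `log(1.8)` so that responding lesions
#' have 1.8-fold higher SUVpeak on average) and residual noise (SD
#' `sigma`). Lesion response labels are drawn from a logistic link on the
#' latent (pre-contrast) log SUV; SUVmax is tied to SUVpeak by a fixed
#' factor > 1, an artifact convention since the joint law of the two
#' metrics is not modeled. Patient-level PSA is lognormal and overall
#' survival is exponential with uniform administrative censoring.
#'
#' Default numeric values reflect the study population the generator
#' emulates: 32 patients with roughly 7-8 analyzed lesions each, baseline
#' site medians around SUV 7-14, ~63% objective lesion response, median
#' PSA 210 ng/mL and median overall survival 10 months.
#'
#' @param n_patients number of patients.
#' @param lesions_per_patient fixed count (scalar) or `c(min, max)` for a
#'   discrete uniform draw.
#' @param site_probs sampling probabilities for metastasis sites.
#' @param site_log_means named per-site mean of log baseline SUVpeak.
#' @param tau between-patient SD of the random intercept (log scale).
#' @param sigma residual SD (log scale).
#' @param responder_log_ratio fixed-effect contrast on log SUVpeak for
#'   responding lesions.
#' @param suv_max_factor SUVmax = `suv_max_factor` * SUVpeak (> 1).
#' @param response_link list: `intercept` and `slope` of the logistic model
#'   for P(lesion responds) given centered latent log SUV;
#'   `p_cr_given_resp` and `p_pd_given_nonresp` split responders into
#'   iCR/iPR and non-responders into iPD/iSD.
#' @param psa_log_params `c(meanlog, sdlog)` of baseline PSA (ng/mL).
#' @param psma_tv_log_params `c(meanlog, sdlog)` of baseline PSMA-TV (mL).
#' @param survival_params list: `median_os_months`, `hr_responder`
#'   (hazard ratio for patient-level responders), `censor_min`,
#'   `censor_max` (uniform censoring window, months).
#' @param seed integer root seed.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(n_patients = 32,
                        lesions_per_patient = 8,
                        site_probs = c(lymph_node = 86, bone = 119,
                                       visceral = 17) / 222,
                        site_log_means = c(prostate = log(13.7),
                                           lymph_node = log(7.4),
                                           bone = log(6.84),
                                           visceral = log(7.33)),
                        tau = 0.4, sigma = 0.5,
                        responder_log_ratio = log(1.8),
                        suv_max_factor = 1.35,
                        response_link = list(intercept = stats::qlogis(149 / 237),
                                             slope = 0,
                                             p_cr_given_resp = 34 / 149,
                                             p_pd_given_nonresp = 28 / 88),
                        psa_log_params = c(meanlog = log(210), sdlog = 1.5),
                        psma_tv_log_params = c(meanlog = log(700), sdlog = 0.8),
                        survival_params = list(median_os_months = 10,
                                               hr_responder = 0.45,
                                               censor_min = 12,
                                               censor_max = 48),
                        seed = 1L) {
  if (!is_scalar_num(n_patients) || n_patients < 1)
    abort("n_patients must be >= 1")
  if (!is_scalar_num(tau) || !is_scalar_num(sigma) || tau < 0 || sigma < 0)
    abort("tau and sigma must be finite and >= 0")
  if (!is_scalar_num(responder_log_ratio))
    abort("responder_log_ratio must be finite")
  if (!is_scalar_num(suv_max_factor) || suv_max_factor <= 1)
    abort("suv_max_factor must be > 1")
  rl <- utils::modifyList(list(intercept = 0, slope = 0,
                               p_cr_given_resp = 0.25,
                               p_pd_given_nonresp = 0.3), response_link)
  probs <- c(rl$p_cr_given_resp, rl$p_pd_given_nonresp)
  if (any(!is.finite(c(rl$intercept, rl$slope, probs))) ||
      any(probs < 0 | probs > 1))
    abort("response_link probabilities must lie in [0, 1]")
  if (any(!is.finite(site_log_means)) || any(!is.finite(psa_log_params)))
    abort("non-finite distribution parameters")
  site_probs <- site_probs / sum(site_probs)
  structure(list(n_patients = as.integer(n_patients),
                 lesions_per_patient = lesions_per_patient,
                 site_probs = site_probs, site_log_means = site_log_means,
                 tau = tau, sigma = sigma,
                 responder_log_ratio = responder_log_ratio,
                 suv_max_factor = suv_max_factor,
                 response_link = rl,
                 psa_log_params = psa_log_params,
                 psma_tv_log_params = psma_tv_log_params,
                 survival_params = survival_params,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a lesion/patient cohort
#'
#' Draws, for patient i and lesion j,
#' `log SUVpeak_ij = site_mean + b_i + beta * R_ij + eps_ij` with
#' `b_i ~ N(0, tau^2)` and `eps_ij ~ N(0, sigma^2)`; the response label
#' `R_ij` is Bernoulli with logit `intercept + slope * (latent - mean)`
#' where the latent value excludes the responder contrast. Response
#' categories, SUVmax, PSA before/after therapy and censored survival
#' times are generated as described in [cohort_spec]. All draws are
#' reproducible from the root seed via derived per-component streams.
#'
#' @param spec a [cohort_spec].
#' @return list with `lesion_table` (one row per lesion: patient_id,
#'   lesion_id, site, suv_peak, suv_max, log_suv_peak, log_suv_max,
#'   response, responder, psma_tv) and `patient_table` (patient_id,
#'   psma_tv, psa_baseline, psa_followup, suv_peak_most_avid,
#'   suv_max_most_avid, n_lesions, patient_responder, os_months, death,
#'   true_intercept).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_patients
  lpp <- spec$lesions_per_patient

  set.seed(derive_seed(spec$seed, 21L))
  n_lesions <- if (length(lpp) == 1) rep.int(as.integer(lpp), n)
               else sample(seq.int(lpp[1], lpp[2]), n, replace = TRUE)
  if (any(n_lesions < 1)) abort("each patient needs at least one lesion")
  b <- stats::rnorm(n, 0, spec$tau)
  patient_id <- rep.int(seq_len(n), n_lesions)
  m <- length(patient_id)
  site <- sample(names(spec$site_probs), m, replace = TRUE,
                 prob = spec$site_probs)
  eps <- stats::rnorm(m, 0, spec$sigma)
  latent <- spec$site_log_means[site] + b[patient_id] + eps
  rl <- spec$response_link
  p_resp <- stats::plogis(rl$intercept + rl$slope * (latent - mean(latent)))
  responder <- stats::runif(m) < p_resp
  u_cat <- stats::runif(m)
  response <- ifelse(responder,
                     ifelse(u_cat < rl$p_cr_given_resp, "iCR", "iPR"),
                     ifelse(u_cat < rl$p_pd_given_nonresp, "iPD", "iSD"))
  log_suv_peak <- unname(latent + spec$responder_log_ratio * responder)
  log_suv_max <- log_suv_peak + log(spec$suv_max_factor)

  set.seed(derive_seed(spec$seed, 22L))
  psma_tv <- stats::rlnorm(n, spec$psma_tv_log_params[1],
                           spec$psma_tv_log_params[2])
  psa0 <- stats::rlnorm(n, spec$psa_log_params[1], spec$psa_log_params[2])
  patient_responder <- vapply(split(responder, patient_id), mean, 0) >= 0.5
  psa_factor <- ifelse(patient_responder,
                       stats::rlnorm(n, log(0.2), 0.5),
                       stats::rlnorm(n, log(1.5), 0.5))
  psa1 <- psa0 * psa_factor

  set.seed(derive_seed(spec$seed, 23L))
  sv <- spec$survival_params
  rate <- log(2) / sv$median_os_months
  t_event <- stats::rexp(n, rate * ifelse(patient_responder, sv$hr_responder, 1))
  t_cens <- stats::runif(n, sv$censor_min, sv$censor_max)
  os <- pmin(t_event, t_cens)
  death <- as.integer(t_event <= t_cens)

  lesion_table <- data.frame(
    patient_id = patient_id,
    lesion_id = unlist(lapply(n_lesions, seq_len), use.names = FALSE),
    site = site,
    suv_peak = exp(log_suv_peak),
    suv_max = exp(log_suv_max),
    log_suv_peak = log_suv_peak,
    log_suv_max = log_suv_max,
    response = factor(response, levels = c("iPD", "iSD", "iPR", "iCR")),
    responder = responder,
    psma_tv = psma_tv[patient_id],
    stringsAsFactors = FALSE
  )
  most_avid <- vapply(split(lesion_table$suv_peak, patient_id), max, 0)
  patient_table <- data.frame(
    patient_id = seq_len(n),
    psma_tv = psma_tv,
    psa_baseline = psa0,
    psa_followup = psa1,
    suv_peak_most_avid = unname(most_avid),
    suv_max_most_avid = unname(most_avid) * spec$suv_max_factor,
    n_lesions = n_lesions,
    patient_responder = unname(patient_responder),
    os_months = os,
    death = death,
    true_intercept = b,
    stringsAsFactors = FALSE
  )
  list(lesion_table = lesion_table, patient_table = patient_table)
}
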