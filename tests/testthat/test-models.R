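sim_rows <- function(seed, n_patients = 60, lesions = 6, tau = 0.4,
                     sigma = 0.5, beta = log(1.8)) {
  spec <- cohort_spec(n_patients = n_patients, lesions_per_patient = lesions,
                      tau = tau, sigma = sigma, responder_log_ratio = beta,
                      seed = seed)
  simulate_cohort(spec)$lesion_table
}

test_that("mixed-model report stores exp(coefficients) bitwise-consistently", {
  rows <- sim_rows(1)
  m <- fit_lmm(rows, "log_suv_peak", "responder")
  expect_identical(m$coefficients$exp_estimate, exp(m$coefficients$estimate))
  expect_identical(m$coefficients$exp_ci_lo, exp(m$coefficients$ci_lo))
  expect_identical(m$coefficients$exp_ci_hi, exp(m$coefficients$ci_hi))
  expect_identical(unname(exp_coef(m)), exp(unname(coef(m))))
  ## ratio-scale reading of the log-scale effects at reporting precision
  expect_equal(round(exp(0.59), 2), 1.80)
  expect_equal(round(exp(0.61), 2), 1.84)
  expect_equal(round(exp(1.28), 1), 3.6)
})

test_that("with no between-patient variance the LMM collapses to OLS", {
  rows <- sim_rows(4, tau = 0)
  m <- fit_lmm(rows, "log_suv_peak", "responder", covariates = "site")
  ols <- stats::lm(log_suv_peak ~ resp + site,
                   data = transform(rows, resp = factor(
                     ifelse(responder, "Responders", "Non-responders"),
                     levels = c("Non-responders", "Responders"))))
  expect_lt(m$tau2, 1e-3)
  expect_equal(unname(coef(m)), unname(stats::coef(ols)), tolerance = 1e-6)
})

test_that("categorical response uses iPD as reference and reports an LRT", {
  rows <- sim_rows(5, n_patients = 80)
  m <- fit_lmm(rows, "log_suv_max", "response")
  expect_true(all(c(".respiSD", ".respiPR", ".respiCR") %in%
                    m$coefficients$term))
  expect_false(any(grepl("respiPD", m$coefficients$term)))
  expect_equal(m$lrt_df, 3)
  expect_lt(m$lrt_p, 0.05)
  expect_gt(m$icc, 0)
  expect_lt(m$icc, 1)
})

test_that("singular fixed-effect designs fail with the collinear term named", {
  rows <- sim_rows(6, n_patients = 20)
  rows$dup <- rows$psma_tv
  expect_error(fit_lmm(rows, "log_suv_peak", "responder",
                       covariates = c("psma_tv", "dup")),
               "collinear.*dup")
  expect_error(fit_lmm(rows[rows$patient_id == 1, ], "log_suv_peak",
                       "responder"), "2 patients")
})

test_that("geometric means match the log-scale derivation", {
  gm <- geometric_means(c(1, 10, 100), rep("a", 3))
  expect_equal(gm$gm, 10)
  set.seed(9)
  x <- stats::rlnorm(50, 2, 0.7)
  g <- geometric_means(x, rep("g", 50))
  expect_equal(g$gm, exp(mean(log(x))))
  se <- stats::sd(log(x)) / sqrt(50)
  expect_equal(g$ci_lo, exp(mean(log(x)) - stats::qt(0.975, 49) * se))
  single <- geometric_means(5, "a")
  expect_true(single$degenerate)
  expect_true(is.na(single$ci_lo))
  expect_error(geometric_means(c(1, 0), c("a", "a")), "positive")
})

test_that("logistic LRT statistic equals a direct likelihood maximization", {
  toy <- data.frame(
    y = c(0, 0, 1, 0, 1, 1, 0, 1, 1, 0, 1, 0),
    v = c(0.2, 1.5, 0.4, 0.3, 1.9, 1.1, 0.8, 0.6, 2.2, 1.0, 1.3, 0.9),
    psma_tv = c(300, 900, 400, 350, 1200, 500, 450, 800, 300, 1000, 600, 700))
  res <- logistic_lrt(toy, "v", covariate = "psma_tv", outcome = "y")
  X1 <- cbind(1, toy$v, toy$psma_tv)
  X0 <- cbind(1, toy$psma_tv)
  ctl <- list(reltol = 1e-14, maxit = 2000)
  o1 <- stats::optim(c(0, 0, 0), function(b) -logistic_loglik(b, X1, toy$y),
                     method = "BFGS", control = ctl)
  o0 <- stats::optim(c(0, 0), function(b) -logistic_loglik(b, X0, toy$y),
                     method = "BFGS", control = ctl)
  want <- 2 * (-o1$value + o0$value)
  expect_equal(res$lrt_stat, want, tolerance = 1e-4)
  expect_equal(res$lrt_df, 1)
  expect_equal(res$or_table$or, exp(res$or_table$estimate))
  expect_false(res$separation)
})

test_that("a perfectly predictive variable raises the separation flag", {
  dat <- data.frame(y = rep(c(0, 1), each = 10),
                    v = rep(c(0, 1), each = 10),
                    psma_tv = stats::runif(20, 200, 1500))
  res <- logistic_lrt(dat, "v", outcome = "y")
  expect_true(res$separation)
  expect_lt(res$lrt_p, 0.001)   # the LRT remains informative
})

test_that("null logistic screens give odds ratios near 1", {
  set.seed(21)
  n <- 400
  dat <- data.frame(y = stats::runif(n) < 0.5,
                    v = stats::rnorm(n),
                    psma_tv = stats::rlnorm(n, log(700), 0.8))
  res <- logistic_lrt(dat, "v", outcome = "y")
  expect_lt(abs(res$or_table$estimate), 3 * res$or_table$se)
  expect_error(logistic_lrt(transform(dat, y = TRUE), "v", outcome = "y"),
               "both classes")
})

test_that("null LRT p-values are not significantly non-uniform", {
  ## 200 seeded null replicates; the Kolmogorov distance must stay below
  ## the 5% critical value 1.358/sqrt(200) for a uniform sample
  p <- numeric(200)
  for (r in 1:200) {
    set.seed(derive_seed(1, 500 + r))
    n <- 100
    dat <- data.frame(psma_tv = stats::rlnorm(n, log(700), 0.8),
                      v = stats::rnorm(n))
    dat$y <- stats::runif(n) <
      stats::plogis(-0.3 + 0.4 * scale(log(dat$psma_tv))[, 1])
    if (length(unique(dat$y)) < 2) dat$y[1:2] <- c(TRUE, FALSE)
    p[r] <- logistic_lrt(dat, "v", outcome = "y")$lrt_p
  }
  sp <- sort(p)
  n <- length(p)
  ks <- max(max(abs(sp - seq_len(n) / n)), max(abs(sp - (seq_len(n) - 1) / n)))
  expect_lt(ks, 1.358 / sqrt(200))
})
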