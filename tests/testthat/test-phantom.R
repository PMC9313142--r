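test_that("noise-free phantom is background everywhere except the aorta", {
  spec <- phantom_spec(grid_shape = c(24, 24, 24), spacing = 2,
                       background_mean = 1, background_sd = 0,
                       aorta = list(mean = 2, sd = 0), seed = 1)
  ph <- generate_phantom(spec)
  expect_equal(nrow(ph$truth), 0)
  expect_true(all(ph$volume$values[!ph$aorta_mask] == 1))
  expect_true(all(ph$volume$values[ph$aorta_mask] == 2))
  expect_true(all(ph$labels == 0L))
})

test_that("discretized sphere volume matches the analytic volume to within a surface layer", {
  spec <- phantom_spec(grid_shape = c(30, 30, 30), spacing = 2,
                       lesions = list(lesion_spec(c(31, 31, 31), 10, 5, "bone")),
                       seed = 1)
  ph <- generate_phantom(spec)
  ## oracle: count voxel centers inside the sphere by direct distance test
  ctr <- (seq_len(30) - 0.5) * 2
  g <- expand.grid(z = ctr, y = ctr, x = ctr)
  inside <- (g$z - 31)^2 + (g$y - 31)^2 + (g$x - 31)^2 <= 100
  expect_equal(ph$truth$true_volume_ml, sum(inside) * 8 / 1000)
  ## one voxel volume per surface voxel bounds the discretization error
  comp <- which(ph$labels == 1L)
  surface <- sum(vapply(comp, function(i) {
    ci <- arrayInd(i, c(30, 30, 30))
    nb <- expand.grid(-1:1, -1:1, -1:1)
    nb <- nb[rowSums(abs(nb)) == 1, ]
    any(vapply(seq_len(nrow(nb)), function(j) {
      p <- ci + unlist(nb[j, ])
      ph$labels[p[1], p[2], p[3]] == 0L
    }, TRUE))
  }, TRUE))
  tol <- surface * 8 / 1000
  expect_lt(abs(ph$truth$true_volume_ml - 4 / 3 * pi * 10^3 / 1000), tol)
})

test_that("geometry is seed-independent while noise is not", {
  mk <- function(seed) generate_phantom(phantom_spec(
    grid_shape = c(20, 20, 20), spacing = 2,
    lesions = list(lesion_spec(c(12, 12, 12), 5, 8, "bone")), seed = seed))
  a <- mk(1); b <- mk(2)
  expect_identical(a$labels, b$labels)
  expect_identical(a$truth, b$truth)
  expect_false(identical(a$volume$values, b$volume$values))
  expect_identical(a$volume$values, mk(1)$volume$values)
})

test_that("invalid phantom geometry is rejected", {
  expect_error(phantom_spec(grid_shape = c(20, 20, 20), spacing = 2,
                            lesions = list(lesion_spec(c(2, 20, 20), 5, 8, "bone"))),
               "outside the grid")
  spec <- phantom_spec(grid_shape = c(20, 20, 20), spacing = 2,
                       lesions = list(lesion_spec(c(14, 20, 20), 6, 8, "bone"),
                                      lesion_spec(c(20, 20, 20), 6, 8, "bone")))
  expect_error(generate_phantom(spec), "overlap")
  expect_error(lesion_spec(c(10, 10, 10), -2, 5, "bone"), "radii")
  expect_error(lesion_spec(c(10, 10, 10), 2, -5, "bone"), "intensity")
})

test_that("simulated log-uptake has the specified moments and ICC", {
  ## 1250 patients x 8 lesions = 1e4 lesions; equal site means isolate the
  ## random-intercept + residual structure
  mu <- 2
  spec <- cohort_spec(n_patients = 1250, lesions_per_patient = 8,
                      site_log_means = c(prostate = mu, lymph_node = mu,
                                         bone = mu, visceral = mu),
                      tau = 0.4, sigma = 0.5,
                      responder_log_ratio = log(1.8), seed = 42)
  tabs <- simulate_cohort(spec)
  lt <- tabs$lesion_table
  resid <- lt$log_suv_peak - mu - log(1.8) * lt$responder
  n <- nrow(lt)
  np <- 1250; k <- 8
  tau2 <- 0.4^2; sig2 <- 0.5^2
  ## clustered standard errors: lesions within a patient share b_i
  se_mean <- sqrt((tau2 + sig2 / k) / np)
  expect_lt(abs(mean(resid)), 3 * se_mean)
  se_var <- sqrt(2 * tau2^2 / np + 2 * sig2^2 / n + 4 * tau2 * sig2 / (k * np))
  expect_lt(abs(stats::var(resid) - (tau2 + sig2)), 3 * se_var)
  ## ICC via the one-way ANOVA estimator (independent of lme4)
  k <- 8
  gm <- tapply(resid, lt$patient_id, mean)
  msb <- k * stats::var(gm)
  msw <- mean(tapply(resid, lt$patient_id, stats::var))
  icc_hat <- (msb - msw) / (msb + (k - 1) * msw)
  expect_lt(abs(icc_hat - 0.4^2 / (0.4^2 + 0.5^2)), 0.05)
})

test_that("responder geometric-mean ratio approaches the generative ratio", {
  spec <- cohort_spec(n_patients = 1000, lesions_per_patient = 8,
                      tau = 0.3, sigma = 0.4,
                      responder_log_ratio = log(1.80), seed = 7)
  lt <- simulate_cohort(spec)$lesion_table
  ## compare within site to remove site-mix confounding
  per_site <- tapply(seq_len(nrow(lt)), lt$site, function(i) {
    mean(lt$log_suv_peak[i][lt$responder[i]]) -
      mean(lt$log_suv_peak[i][!lt$responder[i]])
  })
  ratio <- exp(mean(unlist(per_site)))
  expect_lt(abs(ratio - 1.80), 0.10)
})

test_that("zero-variance cohort collapses to site means and reruns are identical", {
  spec <- cohort_spec(n_patients = 10, lesions_per_patient = 5,
                      tau = 0, sigma = 0, responder_log_ratio = 0, seed = 3)
  tabs <- simulate_cohort(spec)
  lt <- tabs$lesion_table
  for (s in unique(lt$site))
    expect_true(all(lt$suv_peak[lt$site == s] == lt$suv_peak[lt$site == s][1]))
  tabs2 <- simulate_cohort(spec)
  expect_identical(tabs, tabs2)
})

test_that("invalid cohort parameters are rejected", {
  expect_error(cohort_spec(tau = -1), "tau")
  expect_error(cohort_spec(responder_log_ratio = Inf), "finite")
  expect_error(cohort_spec(response_link = list(p_cr_given_resp = 1.4)),
               "\\[0, 1\\]")
  expect_error(cohort_spec(suv_max_factor = 0.9), "suv_max_factor")
})
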