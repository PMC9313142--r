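test_that("lean body mass follows the male Janmahasatian formula", {
  bmi <- 80 / 1.8^2
  expect_equal(lean_body_mass(80, 180), 9270 * 80 / (6680 + 216 * bmi))
  expect_equal(lean_body_mass(80, 180), 61.7314, tolerance = 1e-4)
  ## limit and determinism
  expect_lt(lean_body_mass(1e-6, 180), 1e-5)
  expect_identical(lean_body_mass(92, 175), lean_body_mass(92, 175))
  expect_error(lean_body_mass(-80, 180), "positive")
  expect_error(lean_body_mass(80, 180, sex = "female"), "male")
})

test_that("aorta statistics: constant field, sampling recovery, degenerate VOI", {
  vol <- suv_volume(array(2, c(30, 30, 30)), 2)
  st <- aorta_stats(vol, center = c(30, 30, 30))
  expect_equal(st$suv_mean, 2)
  expect_equal(st$suv_sd, 0)
  expect_equal(st$suv_peak, 2)
  expect_gt(st$voi_voxel_count, 100)

  ph <- generate_phantom(phantom_spec(grid_shape = c(40, 40, 40), spacing = 2,
                                      background_mean = 0.3,
                                      aorta = list(mean = 2, sd = 0.5),
                                      seed = 9))
  st2 <- aorta_stats(ph$volume, center = ph$spec$aorta$center)
  expect_equal(st2$suv_mean, 2, tolerance = 0.1)
  expect_equal(st2$suv_sd, 0.5, tolerance = 0.12)

  ## sub-voxel cylinder holds a single voxel center: SD undefined
  expect_error(aorta_stats(vol, center = c(29, 29, 29), diameter = 1.5,
                           length = 1.5), "SD undefined")
  expect_error(aorta_stats(vol, center = c(4, 30, 30)), "outside the grid")
})

test_that("threshold is 1.5 x aorta peak + 2 x SD", {
  expect_equal(compute_threshold(list(suv_peak = 2, suv_sd = 0.5)), 4)
  expect_equal(compute_threshold(list(suv_peak = 0, suv_sd = 0)), 0)
  expect_error(compute_threshold(list(suv_peak = -1, suv_sd = 0)), "invalid")
  ## phantom-derived stats reproduce the hand computation
  ph <- generate_phantom(phantom_spec(seed = 2))
  st <- aorta_stats(ph$volume, ph$spec$aorta$center)
  expect_identical(compute_threshold(st), 1.5 * st$suv_peak + 2 * st$suv_sd)
})

test_that("suv_peak: constant field, digitized hot-voxel sphere, brute-force equality", {
  vol <- suv_volume(array(3.5, c(20, 20, 20)), 2)
  mask <- array(FALSE, c(20, 20, 20)); mask[8:12, 8:12, 8:12] <- TRUE
  expect_equal(as.numeric(suv_peak(vol, mask)), 3.5)

  ## single hot voxel: peak is the mean over the 123-voxel digitized sphere
  v <- array(1, c(21, 21, 21)); v[11, 11, 11] <- 10
  vol2 <- suv_volume(v, 2)
  m2 <- array(FALSE, dim(v)); m2[11, 11, 11] <- TRUE
  expect_equal(as.numeric(suv_peak(vol2, m2)), (10 + 122) / 123)

  for (seed in 1:3) {
    rv <- random_volume(c(14, 13, 15), spacing = 2, seed = seed)
    set.seed(seed + 100)
    idx <- sample(prod(dim(rv$values)), 40)
    got <- suv_peak(rv, idx)
    want <- brute_suv_peak(rv$values, rv$spacing, idx)
    expect_equal(as.numeric(got), want$value)
    expect_equal(as.vector(attr(got, "center")), as.vector(want$center))
  }
  expect_error(suv_peak(vol, array(FALSE, c(20, 20, 20))), "empty mask")
})

test_that("suv_peak never exceeds the volume maximum", {
  for (seed in 1:20) {
    rv <- random_volume(c(12, 12, 12), spacing = 2, seed = seed)
    set.seed(seed)
    idx <- sample(prod(dim(rv$values)), 25)
    expect_lte(as.numeric(suv_peak(rv, idx)), max(rv$values))
  }
})

test_that("segmentation applies the 0.3 mL filter and strict threshold", {
  ## three lesions of true volume ~0.2 / 0.65 / 1.0 mL, intensities >> T
  spec <- phantom_spec(grid_shape = c(40, 40, 40), spacing = 2,
                       background_mean = 0.2, background_sd = 0,
                       aorta = list(center = c(40, 16, 16), mean = 2, sd = 0),
                       lesions = list(
                         lesion_spec(c(24, 56, 24), 3.63, 20, "bone"),
                         lesion_spec(c(56, 24, 56), 4.93, 25, "lymph_node"),
                         lesion_spec(c(24, 60, 60), 6.21, 30, "bone")),
                       seed = 1)
  ph <- generate_phantom(spec)
  st <- aorta_stats(ph$volume, ph$spec$aorta$center)
  thr <- compute_threshold(st)
  expect_true(all(ph$truth$intensity > thr))
  seg <- segment_lesions(ph$volume, thr, exclusion_mask = ph$aorta_mask)
  expect_equal(nrow(seg$table), 2)
  expect_equal(seg$n_dropped_small, 1)
  expect_true(all(seg$table$volume_ml >= 0.3))

  ## threshold above the global maximum: empty result is valid
  seg0 <- segment_lesions(ph$volume, max(ph$volume$values) + 1)
  expect_equal(nrow(seg0$table), 0)
})

test_that("segmentation equals the flood-fill oracle", {
  for (seed in 1:3) {
    rv <- random_volume(c(20, 20, 20), spacing = 2, seed = seed, hot_frac = 0.3)
    thr <- 2
    seg <- segment_lesions(rv, thr, min_volume_ml = 0, enforce_peak = FALSE)
    want <- flood_components(rv$values > thr, 26)
    got <- labels_to_partition(seg$labels)
    expect_identical(got, want)
  }
})

test_that("raising the threshold never grows a component", {
  rv <- random_volume(c(16, 16, 16), spacing = 2, seed = 11, hot_frac = 0.4)
  t1 <- 1.5; t2 <- 3
  s1 <- segment_lesions(rv, t1, min_volume_ml = 0, enforce_peak = FALSE)
  s2 <- segment_lesions(rv, t2, min_volume_ml = 0, enforce_peak = FALSE)
  for (comp in labels_to_partition(s2$labels)) {
    parents <- unique(s1$labels[comp])
    expect_length(parents, 1)       # stays inside a single coarser component
    expect_true(all(parents > 0))
  }
})

test_that("quantify_scan recovers lesion metrics and burden sums on a phantom", {
  spec <- phantom_spec(grid_shape = c(40, 40, 40), spacing = 2,
                       background_mean = 0.2, background_sd = 0,
                       aorta = list(center = c(40, 16, 16), mean = 2, sd = 0),
                       lesions = list(
                         lesion_spec(c(26, 52, 26), 6, 12, "bone"),
                         lesion_spec(c(56, 26, 56), 5, 8, "lymph_node")),
                       seed = 4)
  ph <- generate_phantom(spec)
  site_labels <- array(0L, dim(ph$labels))
  site_labels[ph$labels == 1] <- 3L   # bone
  site_labels[ph$labels == 2] <- 2L   # lymph_node
  q <- quantify_scan(ph$volume, ph$spec$aorta$center,
                     site_labels = site_labels,
                     site_names = c("prostate", "lymph_node", "bone", "visceral"))
  expect_equal(nrow(q$lesions), 2)
  expect_setequal(q$lesions$site, c("bone", "lymph_node"))
  ## noise-free: suv_max equals the plateau intensity, volumes match truth
  expect_equal(sort(q$lesions$suv_max), sort(ph$truth$intensity))
  expect_equal(sort(q$lesions$volume_ml), sort(ph$truth$true_volume_ml))
  ## additivity identities of the burden metrics
  expect_equal(q$psma_tv_ml, sum(q$lesions$volume_ml))
  expect_equal(q$tl_psma, sum(q$lesions$suv_peak * q$lesions$volume_ml))
  ## global reading available behind the flag
  qg <- quantify_scan(ph$volume, ph$spec$aorta$center,
                      tl_psma_mode = "global")
  expect_equal(qg$tl_psma, max(qg$lesions$suv_peak) * qg$psma_tv_ml)
})

test_that("burden metrics are additive and label-invariant", {
  les <- data.frame(lesion_id = 1:3, suv_peak = c(5, 2, 4),
                    volume_ml = c(10, 20, 3))
  tl <- sum(les$suv_peak * les$volume_ml)
  expect_equal(tl, 5 * 10 + 2 * 20 + 4 * 3)
  perm <- les[c(3, 1, 2), ]
  expect_equal(sum(perm$suv_peak * perm$volume_ml), tl)
  expect_equal(sum(perm$volume_ml), sum(les$volume_ml))
})

test_that("extreme-lesion selection keeps 2 most and 2 least avid per category", {
  les <- data.frame(lesion_id = 1:5, site = "bone", suv_peak = c(1, 2, 3, 4, 5))
  got <- select_extreme_lesions(les)
  expect_setequal(got$suv_peak, c(1, 2, 4, 5))
  ## small categories are kept whole (boundary at 2k)
  les3 <- data.frame(lesion_id = 1:3, site = "bone", suv_peak = 1:3)
  expect_equal(nrow(select_extreme_lesions(les3)), 3)
  les4 <- data.frame(lesion_id = 1:4, site = "bone", suv_peak = 1:4)
  expect_equal(nrow(select_extreme_lesions(les4)), 4)
  ## the single most avid primary prostate lesion is added
  mix <- data.frame(lesion_id = 1:7,
                    site = c(rep("bone", 5), "prostate", "prostate"),
                    suv_peak = c(1, 2, 3, 4, 5, 9, 11))
  got <- select_extreme_lesions(mix)
  expect_equal(got$lesion_id[got$site == "prostate"], 7)
})
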