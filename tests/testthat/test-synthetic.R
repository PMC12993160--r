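test_that("phantom generation is deterministic under a seed", {
  a <- generate_phantom_gt(small_spec(), seed = 5)
  b <- generate_phantom_gt(small_spec(), seed = 5)
  expect_identical(a$gt$data, b$gt$data)
  expect_identical(a$labels$data, b$labels$data)
  c2 <- generate_phantom_gt(small_spec(), seed = 6)
  expect_false(identical(a$gt$data, c2$gt$data))
})

test_that("unperturbed phantom volume matches the analytic ellipsoid volume", {
  spec <- small_spec(perturb_amp = 0)
  ph <- generate_phantom_gt(spec, seed = 7, target_volume_ml = 2.6)
  expect_equal(ph$true_volume_ml, 2.6, tolerance = 0.02)
  # left/right components are disjoint by construction
  expect_equal(sum(ph$labels$data == 1L) + sum(ph$labels$data == 2L),
               sum(ph$gt$data))
})

test_that("phantom volumes track the target distribution", {
  spec <- phantom_spec(shape = c(48, 56, 48))  # default 0.8 mm, 9.13 target
  set.seed(11)
  vols <- replicate(100, generate_phantom_gt(spec)$true_volume_ml)
  expect_lt(abs(mean(vols) - 9.13), 0.5)
  expect_lt(abs(sd(vols) - 1.89), 0.5 * 1.89)
  expect_true(all(abs(vols - 9.13) <= 3 * 1.89 + 0.1))
})

test_that("phantom spec validation catches impossible geometry", {
  expect_error(generate_phantom_gt(
    phantom_spec(shape = c(20, 20, 20), voxel_mm = 1,
                 semi_axes_mm = c(6.5, 16, 10.5))), "grid")
})

test_that("an identity profile reproduces the ground truth exactly", {
  ph <- generate_phantom_gt(small_spec(), seed = 13)
  seg <- simulate_segmentation(ph$gt, segmenter_profile("id"),
                               cohort_mean_ml = ph$true_volume_ml)
  expect_identical(seg$data, ph$gt$data)
  expect_equal(voxel_agreement(overlap_counts(ph$gt, seg))$dsc, 1)
})

test_that("volume targeting hits additive and proportional biases", {
  ph <- generate_phantom_gt(small_spec(), seed = 17, target_volume_ml = 2.6)
  voxml <- 0.001  # 1 mm isotropic
  seg <- simulate_segmentation(
    ph$gt, segmenter_profile("plus2", additive_bias_ml = 0.5), 2.6)
  expect_equal(mask_volume_ml(seg), ph$true_volume_ml + 0.5,
               tolerance = 2 * voxml)
  seg2 <- simulate_segmentation(
    ph$gt, segmenter_profile("prop", proportional_slope = -0.4), 2.0)
  expect_equal(mask_volume_ml(seg2),
               ph$true_volume_ml - 0.4 * (ph$true_volume_ml - 2.0),
               tolerance = 2 * voxml)
})

test_that("sensitivity styles shape the error as advertised", {
  ph <- generate_phantom_gt(small_spec(), seed = 19)
  atlas <- simulate_segmentation(
    ph$gt, segmenter_profile("a", 2, 0, 0, "dilate-into-decoys"),
    ph$true_volume_ml, decoy_labels = ph$labels)
  va <- voxel_agreement(overlap_counts(ph$gt, atlas))
  expect_gt(va$sensitivity, 0.97)   # GT stays contained
  # decoy preference: dilation consumed decoy voxels first
  expect_gt(sum(atlas$data & ph$labels$data >= 3L), 0)
  shrink <- simulate_segmentation(
    ph$gt, segmenter_profile("e", -0.5, 0, 0, "erode-uniform",
                             jitter_frac = 0), ph$true_volume_ml)
  vs <- voxel_agreement(overlap_counts(ph$gt, shrink))
  expect_gt(vs$precision, vs$sensitivity)  # mask inside GT
  expect_equal(vs$precision, 1)
})

test_that("longitudinal erosion reproduces the requested percent change", {
  ph <- generate_phantom_gt(small_spec(), seed = 23)
  fu <- simulate_longitudinal(ph$gt, -1, 1)
  dpct <- 100 * (mask_volume_ml(fu) - ph$true_volume_ml) / ph$true_volume_ml
  expect_gte(dpct, -1.6); expect_lte(dpct, -0.4)
  # rate 0 is the identity
  expect_identical(simulate_longitudinal(ph$gt, 0, 1)$data, ph$gt$data)
  # doubling the interval roughly doubles the change
  fu2 <- simulate_longitudinal(ph$gt, -1, 2)
  dpct2 <- 100 * (mask_volume_ml(fu2) - ph$true_volume_ml) / ph$true_volume_ml
  expect_equal(dpct2, 2 * dpct, tolerance = 0.4)
  expect_error(simulate_longitudinal(ph$gt, -20, 1), "implausible")
})

test_that("clinical generation recovers exact coefficients at zero noise", {
  cfg <- cohort_sim_config(n_subjects = 50, seed = 1,
                           clinical_noise = c(edss = 0, log_t25fw = 0,
                                              log_hpt9 = 0, sdmt = 0))
  set.seed(29)
  n <- 80
  icv <- rnorm(n, 1450, 130)
  z <- (icv - mean(icv)) / sqrt(mean((icv - mean(icv))^2))
  demo <- data.frame(subject_id = 1:n, vol = rnorm(n, 9.13, 1.89),
                     age = rnorm(n, 43.4, 12.4), sex = rbinom(n, 1, 0.5),
                     z_icv = z)
  cl <- simulate_clinical(demo, cfg)
  fit <- lm(cl$truth$edss_star ~ vol + age + sex + z_icv, data = demo)
  expect_equal(unname(coef(fit)["vol"]), -0.26, tolerance = 1e-8)
  # timed tests are right-skewed by construction (log-normal)
  cfgn <- cohort_sim_config(n_subjects = 50, seed = 1)
  cln <- simulate_clinical(demo, cfgn, seed = 31)
  t25 <- cln$table$t25fw
  expect_gt(mean((t25 - mean(t25))^3) / sd(t25)^3, 0)
  # EDSS sits on the half-point lattice in [0, 10]
  expect_true(all(cl$table$edss * 2 == round(cl$table$edss * 2)))
  expect_true(all(cl$table$edss >= 0 & cl$table$edss <= 10))
})

test_that("heteroscedastic switch makes spread grow with the fitted mean", {
  cfg <- cohort_sim_config(n_subjects = 50, seed = 1, heteroscedastic = TRUE)
  set.seed(37)
  n <- 600
  demo <- data.frame(subject_id = 1:n, vol = rnorm(n, 9.13, 1.89),
                     age = rnorm(n, 43.4, 12.4), sex = rbinom(n, 1, 0.5),
                     z_icv = rnorm(n))
  cl <- simulate_clinical(demo, cfg)
  b <- cfg$clinical_betas$edss
  mu <- b["intercept"] + b["vol"] * demo$vol + b["age"] * demo$age +
    b["sex"] * demo$sex + b["z_icv"] * demo$z_icv
  resid <- cl$truth$edss_star - mu
  expect_gt(cor(abs(resid), mu, method = "spearman"), 0.1)
})

test_that("volumes-only cohorts share the mask-level volumetric model", {
  cfg <- cohort_sim_config(n_subjects = 300, seed = 21)
  fas <- generate_cohort(cfg, mask_level = FALSE)
  expect_null(fas$metrics)
  expect_null(fas$containment)
  expect_equal(nrow(fas$cohort), 600)
  # same config twice is identical
  fas2 <- generate_cohort(cfg, mask_level = FALSE)
  expect_identical(fas$cohort, fas2$cohort)
  # profile bias/slope recoverable from the simulated volumes
  bl <- fas$cohort[fas$cohort$timepoint == "baseline", ]
  ba <- bland_altman(bl$vol_gt, bl$vol_atlas_like)
  expect_lt(abs(ba$mean_bias - 5.65), 4 * ba$sd_diff / sqrt(ba$n))
  cal <- calibration_regression(bl$vol_gt, bl$vol_cnn_compressed)
  expect_true(cal$slope_ci_low <= 1 - 0.43 && 1 - 0.43 <= cal$slope_ci_high)
  # clinical truth recovered at FAS size
  f <- fit_crosssectional(fas$cohort, "edss", "gt", hc3 = TRUE)
  expect_true(f$ci_low <= -0.26 && -0.26 <= f$ci_high)
})

test_that("cohort generation is reproducible and writes the documented files", {
  cfg <- cohort_sim_config(n_subjects = 10, seed = 3)
  profiles <- default_segmenter_profiles()[c("atlas_like", "balanced")]
  out1 <- generate_cohort(cfg, profiles, small_spec())
  out2 <- generate_cohort(cfg, profiles, small_spec())
  expect_identical(out1$cohort, out2$cohort)
  expect_identical(out1$truth$subjects, out2$truth$subjects)
  dir <- tempfile("cohort")
  out3 <- generate_cohort(cfg, profiles, small_spec(), out_dir = dir)
  # n x (GT + 2 methods) x 2 timepoints mask files
  expect_length(list.files(dir, pattern = "\\.nii\\.gz$"), 10 * 3 * 2)
  expect_true(file.exists(file.path(dir, "cohort.csv")))
  expect_true(file.exists(file.path(dir, "truth.json")))
  csv <- read.csv(file.path(dir, "cohort.csv"))
  expect_equal(nrow(csv), 20)  # one row per subject-timepoint
  expect_equal(csv$vol_gt, out3$cohort$vol_gt, tolerance = 1e-9)
  # HC subjects draw atrophy near zero, patients near the configured mean
  tl <- out1$truth$subjects
  if (any(tl$dx_group == "HC"))
    expect_lt(max(abs(tl$atrophy_rate_pct_per_year[tl$dx_group == "HC"])), 1)
  expect_lt(mean(tl$atrophy_rate_pct_per_year[tl$dx_group != "HC"]), 0)
})
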