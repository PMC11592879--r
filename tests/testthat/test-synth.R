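test_that("generators are deterministic under a fixed seed", {
  cfg <- synth_eeg_config(duration = 3, ictal_interval = c(1, 2), seed = 11)
  expect_identical(gen_ictal_eeg(cfg)$signals, gen_ictal_eeg(cfg)$signals)

  hcfg <- synth_hippo_config(n_slices = 3, seed = 11)
  a <- gen_hippo_study(hcfg); b <- gen_hippo_study(hcfg)
  expect_identical(a$slices[[2]]$image, b$slices[[2]]$image)

  gcfg <- synth_gm_config(grid_shape = c(16, 16, 16), voxel_size = 6,
                          n_controls = 3, seed = 11)
  expect_identical(gen_gm_cohort(gcfg)$patient_gm,
                   gen_gm_cohort(gcfg)$patient_gm)

  tcfg <- synth_tissue_config(grid_shape = c(6, 6, 6), seed = 11)
  expect_identical(gen_tissue_volume(tcfg)$volume,
                   gen_tissue_volume(tcfg)$volume)
})

test_that("EEG generator plants the configured pair energy ratio", {
  # Monte-Carlo over 25 seeds: mean realized F7-T3/F8-T4 asymmetry over
  # the ictal epoch approaches the planted ratio of 4
  A <- vapply(1:25, function(s) {
    rec <- gen_ictal_eeg(synth_eeg_config(duration = 12,
                                          ictal_interval = c(2, 10),
                                          energy_ratio = 4,
                                          focus_side = "LEFT", seed = s))
    analyze_recording(rec)$pairs$A[2]   # F7-T3 vs F8-T4
  }, numeric(1))
  expect_equal(mean(A), 4, tolerance = 0.1)
})

test_that("a symmetric recording (ratio 1) shows no systematic asymmetry", {
  A <- vapply(1:25, function(s) {
    rec <- gen_ictal_eeg(synth_eeg_config(duration = 8,
                                          ictal_interval = c(1, 7),
                                          energy_ratio = 1, seed = s))
    analyze_recording(rec)$pairs$A
  }, numeric(8))
  expect_equal(mean(A), 1, tolerance = 0.1)
  # lateralization is chance-level: both sides occur across seeds
  sides <- vapply(1:25, function(s) {
    rec <- gen_ictal_eeg(synth_eeg_config(duration = 8,
                                          ictal_interval = c(1, 7),
                                          energy_ratio = 1, seed = s))
    analyze_recording(rec)$recording_side
  }, character(1))
  expect_true(all(c("LEFT", "RIGHT") %in% sides))
})

test_that("EEG config validation rejects bad intervals", {
  expect_error(synth_eeg_config(duration = 5, ictal_interval = c(3, 7)),
               "ictal_interval")
  expect_error(synth_eeg_config(duration = 5, ictal_interval = c(4, 2)),
               "ictal_interval")
  expect_error(synth_eeg_config(energy_ratio = -1))
})

test_that("hippocampus generator volumes follow the configured geometry", {
  sym <- gen_hippo_study(synth_hippo_config(sclerotic_side = "NONE", seed = 2))
  expect_identical(sym$truth$vol_left, sym$truth$vol_right)

  asym <- gen_hippo_study(synth_hippo_config(left_radius = 8, right_radius = 6,
                                             seed = 2))
  expect_lt(asym$truth$vol_right, asym$truth$vol_left)

  expect_error(synth_hippo_config(left_radius = -1), "positive")
  expect_error(synth_hippo_config(n_slices = 0), "positive")
})

test_that("sclerotic side is smaller and brighter", {
  st <- gen_hippo_study(synth_hippo_config(sclerotic_side = "RIGHT",
                                           intensity_boost = 25, seed = 4))
  expect_lt(st$truth$vol_right, st$truth$vol_left)
  f <- extract_features(st)
  expect_gt(f$mean_right, f$mean_left)
})

test_that("GM cohort: controls match the template within noise, blob geometry is right", {
  cfg <- synth_gm_config(grid_shape = c(20, 20, 20), voxel_size = 6,
                         n_controls = 12, atrophy_depth = 0, seed = 7)
  co <- gen_gm_cohort(cfg)
  # per-voxel z-scores of the control mean against its own sd/sqrt(n)
  cm <- Reduce(`+`, co$controls_gm) / length(co$controls_gm)
  # reconstruct the template from a no-noise analogue: the patient with
  # depth 0 differs from the template only by one noise draw, so compare
  # control mean to patient within combined noise instead
  z <- (cm - co$patient_gm) /
    (cfg$control_noise_sd * sqrt(1 / cfg$n_controls + 1))
  expect_lt(mean(abs(z) > 4), 1e-3)

  # planted ball voxel count matches (4/3) pi r^3 / voxel volume
  fine <- gen_gm_cohort(synth_gm_config(grid_shape = c(60, 60, 60),
                                        voxel_size = 1.5, n_controls = 3,
                                        atrophy_radius = 9, seed = 1))
  expected <- 4 / 3 * pi * 9^3 / 1.5^3
  expect_equal(fine$truth$blob_voxels, expected, tolerance = 0.05)
})

test_that("an atrophy ball straddling both hemisphere ROIs is refused", {
  expect_error(
    gen_gm_cohort(synth_gm_config(atrophy_center = c(0, -20, -15),
                                  atrophy_radius = 15, seed = 1)),
    "both hemisphere")
})

test_that("tissue generator handles degenerate mixtures", {
  one <- gen_tissue_volume(synth_tissue_config(class_means = 0.5,
                                               class_sds = 0.05,
                                               grid_shape = c(8, 8, 8)))
  fit <- gmm_segment(one$volume, K = 1)
  expect_equal(fit$means, mean(one$volume))

  # all mass on one class: other components never drawn
  lop <- gen_tissue_volume(synth_tissue_config(class_means = c(0.2, 0.5, 0.8),
                                               class_fractions = c(1, 0, 0),
                                               grid_shape = c(8, 8, 8)))
  expect_true(all(lop$labels == 1))
  expect_error(synth_tissue_config(class_means = numeric(0)), "at least one")
})
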