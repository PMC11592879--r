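test_that("channel energy is the sum of squared samples", {
  expect_equal(channel_energy(c(1, -1, 2)), 6)
  expect_equal(channel_energy(rep(0, 10)), 0)
  set.seed(1)
  x <- rnorm(1000)
  expect_equal(channel_energy(x), oracle_energy(x), tolerance = 1e-9)
  expect_error(channel_energy(numeric(0)), "empty")
})

test_that("asymmetry score is the left/right energy ratio", {
  set.seed(2)
  y <- rnorm(100)
  expect_equal(asymmetry_score(2 * y, y), 4)
  expect_equal(asymmetry_score(y, y), 1)
  expect_equal(asymmetry_score(c(1, 1), c(1, 2)), 0.4)
  x <- rnorm(100)
  expect_equal(asymmetry_score(x, y) * asymmetry_score(y, x), 1)
  expect_error(asymmetry_score(1:3, 1:4), "aligned")
  expect_warning(a <- asymmetry_score(c(1, 2), c(0, 0)), "degenerate|undefined")
  expect_true(is.na(a))
})

test_that("asymmetry score is invariant to common scaling of a pair", {
  set.seed(3)
  xl <- rnorm(50); xr <- rnorm(50)
  for (c in c(0.1, 2, 100)) {
    expect_equal(asymmetry_score(c * xl, c * xr), asymmetry_score(xl, xr))
  }
})

test_that("pair labeling thresholds at A > 1 with ties going negative", {
  expect_identical(pair_label(1.5), 1L)
  expect_identical(pair_label(1.0), -1L)
  expect_identical(pair_label(0.3), -1L)
  expect_identical(pair_label(c(2, 1, NA)), c(1L, -1L, NA))
})

test_that("recording vote: positive label sum means LEFT, ties RIGHT", {
  expect_identical(recording_lateralization(rep(1L, 8)), "LEFT")
  expect_identical(recording_lateralization(c(rep(1L, 4), rep(-1L, 4))), "RIGHT")
  expect_identical(recording_lateralization(rep(-1L, 8)), "RIGHT")
  # degenerate pairs are excluded, not counted
  expect_identical(recording_lateralization(c(1L, NA, NA, NA, NA, NA, NA, NA)),
                   "LEFT")
  expect_error(recording_lateralization(rep(NA_integer_, 8)), "usable")
  expect_error(recording_lateralization(c(1L, 0L)), "must be")
})

test_that("patient vote: strict LEFT majority, ties RIGHT", {
  expect_identical(patient_lateralization(c("LEFT", "LEFT", "RIGHT")), "LEFT")
  expect_identical(patient_lateralization(c("LEFT", "RIGHT")), "RIGHT")
  expect_identical(patient_lateralization("RIGHT"), "RIGHT")
  expect_error(patient_lateralization(character(0)), "at least one")
})

test_that("swapping left and right channels inverts scores and the decision", {
  rec <- gen_ictal_eeg(synth_eeg_config(duration = 8, ictal_interval = c(2, 7),
                                        energy_ratio = 3, focus_side = "LEFT",
                                        seed = 9))
  res <- analyze_recording(rec)
  pt <- symmetric_pair_table()
  swapped <- rec
  li <- match(pt$left, rec$channel_names)
  ri <- match(pt$right, rec$channel_names)
  swapped$signals[c(li, ri), ] <- rec$signals[c(ri, li), ]
  res2 <- analyze_recording(swapped)
  expect_equal(res2$pairs$A, 1 / res$pairs$A)
  expect_false(res2$recording_side == res$recording_side)
})

test_that("planted focus side is recovered on strongly lateralized recordings", {
  for (s in 1:10) {
    side <- if (s %% 2 == 0) "LEFT" else "RIGHT"
    rec <- gen_ictal_eeg(synth_eeg_config(duration = 10,
                                          ictal_interval = c(1, 9),
                                          energy_ratio = 4,
                                          focus_side = side, seed = s))
    expect_identical(analyze_recording(rec)$recording_side, side)
  }
})

test_that("sub-epoch voting agrees with the planted side", {
  rec <- gen_ictal_eeg(synth_eeg_config(duration = 10, ictal_interval = c(1, 9),
                                        energy_ratio = 4, focus_side = "RIGHT",
                                        seed = 21))
  res <- analyze_recording(rec, epoch_len = 2)
  expect_identical(res$recording_side, "RIGHT")
})

test_that("patient-level analysis aggregates recordings by majority", {
  recs <- lapply(1:3, function(s) {
    gen_ictal_eeg(synth_eeg_config(duration = 8, ictal_interval = c(1, 7),
                                   energy_ratio = 4, focus_side = "LEFT",
                                   seed = s))
  })
  out <- eeg_lateralize(recs)
  expect_identical(out$patient_side, "LEFT")
  expect_length(out$recording_sides, 3)
})
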