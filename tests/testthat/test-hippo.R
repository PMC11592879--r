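test_that("mask binarization recovers masks and matches a pixel-count oracle", {
  img <- matrix(5, 10, 10)
  expect_false(any(binarize_mask(img, 128)))

  set.seed(4)
  mask <- matrix(runif(100) > 0.5, 10, 10)
  expect_identical(binarize_mask(mask * 255, 128), mask)

  rimg <- matrix(runif(400, 0, 255), 20, 20)
  bm <- binarize_mask(rimg, 100)
  cnt <- 0L
  for (v in rimg) if (v > 100) cnt <- cnt + 1L
  expect_identical(sum(bm), cnt)
})

test_that("Otsu default threshold separates a bimodal overlay", {
  set.seed(5)
  mask <- matrix(FALSE, 30, 30); mask[10:20, 10:20] <- TRUE
  img <- matrix(rnorm(900, 30, 5), 30, 30)
  img[mask] <- rnorm(sum(mask), 200, 5)
  expect_identical(binarize_mask(img), mask)
})

test_that("region area is pixel count times pixel area", {
  m <- matrix(FALSE, 20, 20); m[1:10, 1:10] <- TRUE
  expect_equal(region_area(m, 0.25), 25)
  expect_equal(region_area(matrix(FALSE, 5, 5), 1), 0)
  # w x h rectangle closed form
  r <- matrix(FALSE, 12, 12); r[2:5, 3:9] <- TRUE   # 4 x 7
  expect_equal(region_area(r, 0.5), 4 * 7 * 0.5)
})

test_that("region volume sums per-slice areas times thickness", {
  expect_equal(region_volume(c(25, 25, 0), 2), 100)
  expect_equal(region_volume(7, 3), 21)
  expect_error(region_volume(numeric(0), 2), "at least one")
  expect_error(region_volume(c(1, 2), -1), "positive")
})

test_that("generator true volumes equal the measured feature volumes exactly", {
  st <- gen_hippo_study(synth_hippo_config(n_slices = 5, seed = 6))
  f <- extract_features(st)
  expect_identical(f$vol_left, st$truth$vol_left)
  expect_identical(f$vol_right, st$truth$vol_right)
})

test_that("region statistics use the N-1 denominator and match a loop oracle", {
  img <- matrix(c(2, 4, 6, 99), 2, 2)
  msk <- matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2)
  s <- region_stats(img, msk)
  expect_equal(s$mu, 4)
  expect_equal(s$sigma, 2)

  cimg <- matrix(7, 4, 4)
  expect_equal(region_stats(cimg, matrix(TRUE, 4, 4))$sigma, 0)

  set.seed(7)
  rimg <- matrix(rnorm(100, 50, 10), 10, 10)
  rmsk <- matrix(runif(100) > 0.4, 10, 10)
  got <- region_stats(rimg, rmsk)
  want <- oracle_region_stats(rimg, rmsk)
  expect_equal(got$mu, want$mu, tolerance = 1e-9)
  expect_equal(got$sigma, want$sigma, tolerance = 1e-9)

  expect_error(region_stats(rimg, matrix(FALSE, 10, 10)), "empty")
  one <- matrix(FALSE, 10, 10); one[1, 1] <- TRUE
  expect_warning(s1 <- region_stats(rimg, one), "undefined")
  expect_true(is.na(s1$sigma))
})

test_that("volume is additive over disjoint mask parts", {
  set.seed(8)
  m <- matrix(runif(400) > 0.5, 20, 20)
  top <- m; top[11:20, ] <- FALSE
  bot <- m; bot[1:10, ] <- FALSE
  a <- function(msk) region_volume(region_area(msk, 0.3), 2.5)
  expect_equal(a(top) + a(bot), a(m))
})

test_that("intensity shift moves the mean and leaves sigma unchanged", {
  set.seed(9)
  img <- matrix(rnorm(100, 80, 12), 10, 10)
  msk <- matrix(runif(100) > 0.3, 10, 10)
  s0 <- region_stats(img, msk)
  s1 <- region_stats(img + 17, msk)
  expect_equal(s1$mu, s0$mu + 17)
  expect_equal(s1$sigma, s0$sigma)
})

test_that("feature extraction averages stats across slices and sums volumes", {
  st <- gen_hippo_study(synth_hippo_config(n_slices = 1, seed = 10))
  st2 <- st
  st2$slices <- c(st$slices, st$slices)   # duplicate the single slice
  f1 <- extract_features(st)
  f2 <- extract_features(st2)
  expect_equal(f2$mean_left, f1$mean_left)
  expect_equal(f2$sd_right, f1$sd_right)
  expect_equal(f2$vol_left, 2 * f1$vol_left)

  # symmetric study: identical masks left/right up to position
  sym <- gen_hippo_study(synth_hippo_config(sclerotic_side = "NONE",
                                            noise_sd = 0.01, seed = 11))
  fs <- extract_features(sym)
  expect_equal(fs$vol_left, fs$vol_right)
  expect_equal(fs$mean_left, fs$mean_right, tolerance = 1e-3)
})
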