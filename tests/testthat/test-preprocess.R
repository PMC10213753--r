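test_that("resampling preserves identity, constants and extent", {
  vol <- array(rnorm(16 * 12 * 4), c(16, 12, 4))
  same <- resampleToSpacing(vol, c(1, 1, 4), c(1, 1, 4), "linear")
  expect_identical(same$data, vol)
  const <- resampleToSpacing(array(7, c(10, 10, 3)), c(2, 2, 5),
                             c(0.7, 1.3, 2), "linear")
  expect_equal(range(const$data), c(7, 7))
  # physical extent within one output voxel per axis
  d <- dim(const$data)
  expect_lt(max(abs((d - 1) * c(0.7, 1.3, 2) - (c(10, 10, 3) - 1) *
                      c(2, 2, 5))), max(c(0.7, 1.3, 2)))
  expect_error(resampleToSpacing(vol, c(1, 1, -1), c(1, 1, 1)), "positive")
  expect_error(resampleToSpacing(vol, c(1, 1, 4), c(100, 100, 100)),
               "< 2 voxels")
})

test_that("nearest-resampled disk matches the analytic rasterization", {
  # 10 mm disk at 1 mm spacing, resampled to 0.5 mm
  n <- 31
  coords <- (seq_len(n) - 1) - 15
  disk <- outer(coords, coords, function(a, b) (a^2 + b^2 <= 100) * 1)
  vol <- array(disk, c(n, n, 2))
  out <- resampleToSpacing(vol, c(1, 1, 1), c(0.5, 0.5, 1), "nearest")
  m <- dim(out$data)[1]
  fine <- (seq_len(m) - 1) * 0.5 - 15
  oracle <- outer(fine, fine, function(a, b) (a^2 + b^2 <= 100) * 1)
  expect_true(all(out$data %in% c(0, 1)))
  expect_gte(diceCoef(out$data[, , 1], oracle), 0.95)
})

test_that("smooth-divisor bias correction reduces inhomogeneity", {
  cfg <- preprocessConfig(biasMethod = "smooth_div")
  flat <- array(50, c(32, 32, 4))
  out <- correctBiasField(flat, cfg, spacing = c(1, 1, 4))
  expect_lt(max(abs(out - 50)) / 50, 0.01)
  expect_identical(correctBiasField(flat, preprocessConfig(biasMethod =
                                                             "none")), flat)
  case <- cachedCase("clean7", cleanSpec(), 7L)
  biased <- applyBiasField(imageData(case), 0.4, 20,
                           voxelSpacing(case), 11L)
  corrected <- correctBiasField(biased, cfg, spacing = voxelSpacing(case))
  core <- rectseg:::erodeMask(labelData(case) == 3, 1)
  cv <- function(v) sd(v[core]) / mean(v[core])
  expect_lt(cv(corrected), cv(biased))
})

test_that("muscle normalization fixes the reference mean at one", {
  case <- cachedCase("clean7", cleanSpec(), 7L)
  img <- imageData(case)
  mask <- labelData(case) == 4
  norm <- normalizeByMuscle(img, mask)
  expect_equal(mean(norm[mask]), 1, tolerance = 1e-12)
  # scale invariance
  expect_equal(normalizeByMuscle(img * 3, mask), norm, tolerance = 1e-12)
  # idempotence
  expect_equal(normalizeByMuscle(norm, mask), norm, tolerance = 1e-12)
  # own full-support mask: global mean 1
  expect_equal(mean(normalizeByMuscle(img, img > -Inf)), 1,
               tolerance = 1e-12)
  # exact intensity ratio: muscle at 100, wall at 60 -> normalized wall 0.6
  vol <- array(30, c(20, 20, 2))
  muscle <- array(FALSE, dim(vol)); muscle[3:6, 3:6, ] <- TRUE
  wall <- array(FALSE, dim(vol)); wall[12:16, 12:16, ] <- TRUE
  vol[muscle] <- 100; vol[wall] <- 60
  nv <- normalizeByMuscle(vol, muscle)
  expect_equal(mean(nv[muscle]), 1, tolerance = 1e-12)
  expect_equal(mean(nv[wall]), 0.6, tolerance = 1e-12)
  expect_error(normalizeByMuscle(img, mask & FALSE), "empty")
})

test_that("center-crop/resize honors its geometric contracts", {
  cfg <- preprocessConfig(cropFraction = 1, netInputSize = 128L)
  x <- matrix(rnorm(128 * 128), 128, 128)
  out <- centerCropResize(x, cfg)
  expect_equal(unclass(out), x, ignore_attr = TRUE)
  # nearest keeps only input values
  m <- matrix(sample(c(0L, 3L), 90 * 70, TRUE), 90, 70)
  mOut <- centerCropResize(m, preprocessConfig(cropFraction = 0.8,
                                               netInputSize = 32L),
                           isMask = TRUE)
  expect_true(all(mOut %in% c(0L, 3L)))
  # 256 disk, crop 0.5, resize 128: 1:1 effective scale preserves area
  co <- (seq_len(256) - 1) - 127.5
  disk <- outer(co, co, function(a, b) (a^2 + b^2 <= 40^2) * 1)
  cfg2 <- preprocessConfig(cropFraction = 0.5, netInputSize = 128L)
  dOut <- centerCropResize(disk, cfg2, isMask = TRUE)
  expect_lt(abs(sum(dOut) - sum(disk)) / sum(disk), 0.05)
  expect_error(centerCropResize(matrix(1, 2, 2),
                                preprocessConfig(cropFraction = 0.6,
                                                 netInputSize = 16L)),
               "crop window")
})

test_that("uncropping inverts the crop geometry", {
  cfg <- preprocessConfig(cropFraction = 0.5, netInputSize = 128L)
  co <- (seq_len(256) - 1) - 127.5
  disk <- outer(co, co, function(a, b) (a^2 + b^2 <= 40^2) * 1)
  cropped <- centerCropResize(disk, cfg, isMask = TRUE)
  mapping <- attr(cropped, "cropMapping")
  back <- uncropPrediction(cropped, mapping, isMask = TRUE)
  expect_gte(diceCoef(back, disk), 0.98)
  # a genuinely rescaled path still round-trips well
  cfg3 <- preprocessConfig(cropFraction = 0.7, netInputSize = 96L)
  cropped3 <- centerCropResize(disk, cfg3, isMask = TRUE)
  back3 <- uncropPrediction(cropped3, attr(cropped3, "cropMapping"),
                            isMask = TRUE)
  expect_gte(diceCoef(back3, disk), 0.98)
  zero <- uncropPrediction(matrix(0, 128, 128), mapping, isMask = TRUE)
  expect_equal(sum(zero), 0)
  expect_error(uncropPrediction(matrix(0, 64, 64), mapping), "geometry")
})

test_that("the full chain leaves labels integral and muscle mean unit", {
  case <- generatePhantom(smallSpec(voxelSpacing = c(1, 1, 4)), 21L)
  cfg <- preprocessConfig(targetSpacing = c(0.781, 0.781, 4),
                          cropFraction = 1, netInputSize = 64L)
  pc <- preprocessCase(case, cfg)
  expect_true(all(pc$labels %in% 0:4))
  expect_equal(pc$spacing, c(0.781, 0.781, 4))
  expect_equal(mean(pc$image[pc$labels == 4]), 1, tolerance = 1e-12)
})
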