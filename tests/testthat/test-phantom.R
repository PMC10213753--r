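test_that("generation is deterministic and anatomically complete", {
  spec <- smallSpec()
  a <- cachedCase("det1", spec, 42L)
  b <- generatePhantom(spec, 42L)
  expect_identical(imageData(a), imageData(b))
  expect_identical(labelData(a), labelData(b))
  expect_true(all(1:4 %in% labelData(a)))
  c2 <- generatePhantom(spec, 43L)
  expect_false(identical(imageData(a), imageData(c2)))
})

test_that("noiseless region cores carry their configured intensities", {
  case <- cachedCase("clean7", cleanSpec(), 7L)
  lab <- labelData(case); img <- imageData(case)
  intens <- c(lumen = 168, wall = 70, fat = 140, muscle = 100)
  for (l in c(1, 2, 3, 4)) {
    core <- rectseg:::erodeMask(lab == l, 2)
    if (!any(core)) core <- rectseg:::erodeMask(lab == l, 1)
    expect_gt(sum(core), 0)
    expect_equal(mean(img[core]), unname(intens[l]), tolerance = 1e-8)
  }
})

test_that("rasterized lumen area matches the analytic generating disk", {
  # degenerate ranges pin the geometry: disk radius 5 mm at 1 mm spacing
  spec <- phantomSpec(gridShape = c(64L, 64L, 5L),
                      voxelSpacing = c(1, 1, 4),
                      lumenRadiusRange = c(5, 5),
                      wallThicknessRange = c(2, 2),
                      fatRingThicknessRange = c(4, 4),
                      deformMagnitude = 0, anisotropyRange = c(1, 1),
                      muscleOffset = 22, muscleRadius = 3,
                      noiseSigma = 0, biasAmplitude = 0)
  for (seed in 1:5) {
    lab <- labelData(generatePhantom(spec, seed))
    central <- lab[, , 3]  # through-slice scaling is 1 at the center slice
    expect_equal(sum(central == 1), pi * 25, tolerance = 0.1)
  }
})

test_that("nesting and label partition hold on every slice", {
  case <- cachedCase("det1", smallSpec(), 42L)
  lab <- labelData(case)
  expect_true(all(lab %in% 0:4))
  for (k in seq_len(dim(lab)[3])) {
    sl <- lab[, , k]
    lumen <- sl == 1; rectum <- sl %in% 1:2; withFat <- sl %in% 1:3
    expect_true(all(withFat[rectum]))
    expect_true(all(rectum[lumen]))
    expect_false(any(sl == 4 & sl %in% 1:3))
  }
})

test_that("increasing noise strictly lowers the wall/lumen contrast-to-noise",
{
  cnr <- vapply(c(0.02, 0.08, 0.2), function(ns) {
    case <- generatePhantom(smallSpec(noiseSigma = ns, biasAmplitude = 0,
                                      gelMode = TRUE), 5L)
    lab <- labelData(case); img <- imageData(case)
    lcore <- rectseg:::erodeMask(lab == 1, 1)
    wcore <- rectseg:::erodeMask(lab == 2, 1)
    abs(mean(img[lcore]) - mean(img[wcore])) /
      sqrt((sd(img[lcore])^2 + sd(img[wcore])^2) / 2)
  }, numeric(1))
  expect_true(all(diff(cnr) < 0))
})

test_that("gel and quality modes move the configured contrasts", {
  gel <- smallSpec(gelMode = TRUE)
  nogel <- smallSpec(gelMode = FALSE)
  expect_gte(gel@regionIntensities[["lumen"]],
             2 * gel@regionIntensities[["wall"]])
  expect_lt(abs(nogel@regionIntensities[["lumen"]] -
                  nogel@regionIntensities[["wall"]]),
            0.1 * nogel@regionIntensities[["wall"]])
  deg <- smallSpec(qualityMode = "degraded")
  expect_equal(deg@noiseSigma, 2 * gel@noiseSigma)
  expect_lt(deg@regionIntensities[["fat"]] - deg@regionIntensities[["wall"]],
            gel@regionIntensities[["fat"]] - gel@regionIntensities[["wall"]])
})

test_that("bias field corruption respects its bounds and identity case", {
  img <- array(50, c(20, 20, 4))
  expect_identical(applyBiasField(img, 0, 30, c(1, 1, 4), 1L), img)
  out <- applyBiasField(img, 0.4, 10, c(1, 1, 4), 1L)
  expect_gte(min(out), 30)
  expect_lte(max(out), 70)
  expect_gt(max(out) - min(out), 1)  # the field actually varies
  out2 <- applyBiasField(img, 0.4, 10, c(1, 1, 4), 1L)
  expect_identical(out, out2)
})

test_that("institution shift is affine on the image and inert on labels", {
  case <- cachedCase("clean7", cleanSpec(), 7L)
  expect_equal(imageData(shiftInstitution(case, 1, 0)), imageData(case))
  sh <- shiftInstitution(case, 2, 10)
  lab <- labelData(case)
  mcore <- rectseg:::erodeMask(lab == 4, 2)
  expect_equal(mean(imageData(sh)[mcore]), 210, tolerance = 1e-8)
  expect_identical(labelData(sh), lab)
})

test_that("cohorts derive per-case seeds and round-trip through NIfTI", {
  spec <- smallSpec()
  coh <- generateCohort(spec, 5, 7L, split = "test", prefix = "t")
  expect_equal(nrow(coh$manifest), 5)
  imgs <- lapply(coh$cases, imageData)
  for (i in 1:4) for (j in (i + 1):5)
    expect_false(identical(imgs[[i]], imgs[[j]]))
  coh2 <- generateCohort(spec, 5, 7L, split = "test", prefix = "t")
  expect_identical(imgs, lapply(coh2$cases, imageData))
  one <- generateCohort(spec, 1, 3L)
  expect_equal(nrow(one$manifest), 1)

  dir <- withr::local_tempdir()
  man <- writeCohort(generateCohort(spec, 2, 9L), dir)
  back <- readCohort(file.path(dir, "manifest.csv"))
  orig <- generateCohort(spec, 2, 9L)$cases
  expect_equal(labelData(back$cases[[1]]), labelData(orig[[1]]))
  expect_equal(imageData(back$cases[[2]]), imageData(orig[[2]]),
               tolerance = 1e-6)
  expect_equal(voxelSpacing(back$cases[[1]]), voxelSpacing(orig[[1]]),
               tolerance = 1e-6)
})

test_that("impossible anatomy and bad parameters are rejected", {
  expect_error(smallSpec(fatRingThicknessRange = c(30, 40)), "fit")
  expect_error(smallSpec(biasAmplitude = 1.2), "biasAmplitude")
  expect_error(smallSpec(noiseSigma = -1), "noiseSigma")
  expect_error(applyBiasField(array(1, c(4, 4, 2)), 1.5, 10, c(1, 1, 1), 1L))
  expect_error(shiftInstitution(cachedCase("clean7", cleanSpec(), 7L), -1))
})
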