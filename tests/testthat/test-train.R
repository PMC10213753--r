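test_that("region targets implement the boundary-task definitions", {
  lab <- matrix(0L, 12, 12)
  lab[4:9, 4:9] <- 3L          # fat block
  lab[5:8, 5:8] <- 2L          # wall
  lab[6:7, 6:7] <- 1L          # lumen
  lab[1:2, 1:2] <- 4L          # muscle, must never appear
  wall <- makeRegionTarget(lab, "wall")
  lumen <- makeRegionTarget(lab, "lumen")
  fat <- makeRegionTarget(lab, "fat")
  annulus <- makeRegionTarget(lab, "wall_annulus")
  expect_equal(sum(wall), 16)          # union of lumen (4) and wall (12)
  expect_equal(sum(lumen), 4)
  expect_equal(sum(annulus), 12)
  expect_true(all(wall[lumen == 1] == 1))      # nesting
  expect_equal(sum(fat[lab == 4]), 0)
  expect_equal(sum(wall[lab == 4]), 0)
  # absent region gives a valid empty mask
  expect_equal(sum(makeRegionTarget(matrix(0L, 4, 4), "fat")), 0)
  expect_error(makeRegionTarget(lab, "tumor"), "region")
})

test_that("soft Dice loss matches its closed forms", {
  t <- matrix(0, 10, 10); t[3:6, 3:6] <- 1
  expect_lt(diceLoss(t, t), 1e-6)
  expect_gt(diceLoss(t * 0, t), 1 - 1e-3)
  # uniform 0.5 prediction over a half-covering target -> loss 0.5
  t2 <- matrix(0, 10, 10); t2[, 1:5] <- 1
  p2 <- matrix(0.5, 10, 10)
  expect_equal(diceLoss(p2, t2), 0.5, tolerance = 1e-5)
  expect_error(diceLoss(p2, matrix(1, 3, 3)), "shape")
})

test_that("Dice loss is symmetric on hard masks, matching the overlap metric", {
  set.seed(42)
  for (i in 1:20) {
    a <- randomBlobMask(24, seed = i)
    b <- randomBlobMask(24, seed = i + 100)
    expect_equal(diceLoss(a, b), diceLoss(b, a), tolerance = 1e-12)
    expect_equal(1 - diceLoss(a, b), diceCoef(a, b), tolerance = 1e-5)
  }
})

test_that("multiclass loss averages soft Dice over non-background classes", {
  lab <- matrix(0L, 8, 8); lab[2:4, 2:4] <- 1L; lab[6:8, 6:8] <- 2L
  onehot <- rectseg:::.oneHot(lab, 4L)
  expect_lt(diceLoss(onehot, lab), 1e-5)
  # perfect classes 1..2, absent class 3 contributes ~0 loss via smoothing
  worst <- onehot; worst[, , 2] <- 0
  expect_gt(diceLoss(worst, lab), 0.3)
})

test_that("augmentation applies one shared transform with mask integrity", {
  img <- matrix(rnorm(40 * 40), 40, 40)
  msk <- matrix(0, 40, 40); msk[15:25, 18:28] <- 1
  id <- augmentPair(img, msk, flipProb = 0, rotRange = c(0, 0), seed = 1L)
  expect_identical(id$image, img)
  expect_identical(id$mask, msk)
  # flipping twice is the identity
  f1 <- augmentPair(img, msk, flipProb = 1, rotRange = c(0, 0), seed = 2L)
  f2 <- augmentPair(f1$image, f1$mask, flipProb = 1, rotRange = c(0, 0),
                    seed = 3L)
  expect_identical(f2$image, img)
  expect_identical(f2$mask, msk)
  # a centered disk keeps its area under rotation, and the mask stays binary
  co <- (seq_len(64) - 1) - 31.5
  disk <- outer(co, co, function(a, b) (a^2 + b^2 <= 15^2) * 1)
  for (seed in 1:5) {
    rot <- augmentPair(disk, disk, flipProb = 0, rotRange = c(-30, 30),
                       seed = seed)
    expect_true(all(rot$mask %in% c(0, 1)))
    expect_lt(abs(sum(rot$mask) - sum(disk)) / sum(disk), 0.05)
  }
})

test_that("training overfits a trivial dataset and keeps its contracts", {
  # one repeated synthetic slice, dropout off: the loss must collapse
  case <- generatePhantom(
    phantomSpec(gridShape = c(32L, 32L, 4L), voxelSpacing = c(1.2, 1.2, 4),
                lumenRadiusRange = c(2.5, 4), wallThicknessRange = c(1.5, 2),
                fatRingThicknessRange = c(2.5, 3.5), muscleOffset = 13.5,
                muscleRadius = 2.2, noiseSigma = 0, biasAmplitude = 0,
                deformMagnitude = 0), 7L)
  pp <- preprocessConfig(targetSpacing = c(1.2, 1.2, 4), cropFraction = 1,
                         netInputSize = 32L)
  pc <- preprocessCase(case, pp)
  img <- centerCropResize(pc$image[, , 2], pp)
  tgt <- centerCropResize(makeRegionTarget(pc$labels[, , 2], "wall"), pp,
                          isMask = TRUE)
  ds <- list(images = array(rep(img, 32), c(32, 32, 32)),
             targets = array(rep(tgt, 32), c(32, 32, 32)),
             caseIds = rep("c1", 32), sliceIdx = 1:32, region = "wall")
  cfg <- trainConfig(epochs = 50L, batchSize = 8L, seed = 5L,
                     augFlipProb = 0, augRotRange = c(0, 0))
  model <- buildUNet(unetConfig(inputSize = 32L, depth = 2L,
                                baseFilters = 8L, dropoutRate = 0),
                     seed = 4L)
  fit <- trainModel(model, ds, valData = NULL, cfg)
  expect_equal(nrow(fit$history), 50)
  expect_lt(tail(fit$history$train_loss, 1), 0.1)
  # the last stretch of the loss curve is essentially non-increasing
  lastTen <- tail(fit$history$train_loss, 10)
  expect_lt(tail(lastTen, 1), head(lastTen, 1) + 0.02)
  expect_true(fit$model@trained)
  # history length contract and seeded reproducibility on a short run
  short <- trainConfig(epochs = 2L, batchSize = 8L, seed = 9L)
  f1 <- trainModel(model, ds, ds, short)
  f2 <- trainModel(model, ds, ds, short)
  expect_equal(nrow(f1$history), 2)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model@params, f2$model@params)
  expect_error(trainModel(model, list(images = array(0, c(64, 64, 0))),
                          NULL, short), "empty")
})
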