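test_that("binarization respects threshold semantics and monotonicity", {
  hard <- matrix(sample(c(0, 1), 64, TRUE), 8, 8)
  expect_equal(binarize(hard, 0.5), hard)
  expect_equal(sum(binarize(matrix(0.3, 5, 5), 0.5)), 0)
  p <- matrix(runif(100), 10, 10)
  expect_true(all(binarize(p, 0.8) <= binarize(p, 0.2)))
  expect_error(binarize(p, 0))
  pm <- new("ProbabilityMap", values = array(1 / 4, c(4, 4, 4)),
            head = "softmax", geometry = list())
  expect_error(binarize(pm, 0.5), "softmax")
})

test_that("softmax maps decode to exclusive masks partitioning the image", {
  v <- array(0, c(6, 6, 3))
  v[, , 1] <- 0.2; v[, , 2] <- 0.5; v[, , 3] <- 0.3
  v[1:3, , 2] <- 0.1; v[1:3, , 3] <- 0.7
  pm <- new("ProbabilityMap", values = v / rep(apply(v, c(1, 2), sum),
                                               times = 3),
            head = "softmax", geometry = list())
  masks <- multiclassToMasks(pm)
  expect_length(masks, 2)
  overlap <- masks[[1] ] * masks[[2]]
  expect_equal(sum(overlap), 0)
  # one-hot input returns the exact channels
  oh <- array(0, c(4, 4, 3)); oh[, , 2] <- 1
  m2 <- multiclassToMasks(oh)
  expect_equal(sum(m2[[1]]), 16)
  # uniform map: deterministic lowest-index tie-break = background wins
  uni <- array(1 / 3, c(4, 4, 3))
  m3 <- multiclassToMasks(uni)
  expect_equal(sum(m3[[1]]) + sum(m3[[2]]), 0)
  expect_error(multiclassToMasks(matrix(0.5, 4, 4)), "H x W x K")
})

test_that("largest-component retention keeps exactly the biggest blob", {
  m <- matrix(0, 20, 20)
  m[2:11, 2:6] <- 1          # 50 voxels
  m[15:16, 15:18] <- 1       # 8 voxels, clipped to 7 below
  m[15, 15] <- 0
  out <- largestComponent(m)
  expect_equal(sum(out), 50)
  expect_equal(sum(out[2:11, 2:6]), 50)
  single <- largestComponent(out)
  expect_equal(single, out)
  expect_equal(sum(largestComponent(matrix(0, 5, 5))), 0)
  # output is a subset with at most one component
  set.seed(3)
  for (i in 1:10) {
    r <- matrix(runif(400) > 0.7, 20, 20) * 1
    lc <- largestComponent(r)
    expect_true(all(lc <= r))
    lab <- rectseg:::.labelComponents(lc > 0, dim(lc), 8L)
    expect_lte(attr(lab, "ncomp"), 1)
  }
  # 8- vs 4-connectivity: a diagonal pair is one component only under 8
  dg <- matrix(0, 5, 5); dg[2, 2] <- 1; dg[3, 3] <- 1
  expect_equal(sum(largestComponent(dg, 8L)), 2)
  expect_equal(sum(largestComponent(dg, 4L)), 1)
  # 3D connectivity across slices
  v <- array(0, c(4, 4, 2)); v[1, 1, 1] <- 1; v[2, 2, 2] <- 1; v[4, 4, 2] <- 1
  expect_equal(sum(largestComponent(v, 26L)), 2)
})

test_that("threshold optimization maximizes validation Dice, ties to smallest", {
  # oracle probabilities equal to the target: every threshold scores 1,
  # the tie-break returns the smallest grid point
  t1 <- matrix(0, 16, 16); t1[5:10, 5:10] <- 1
  t2 <- matrix(0, 16, 16); t2[2:7, 9:14] <- 1
  valData <- list(images = array(0, c(16, 16, 2)),
                  targets = array(c(t1, t2), c(16, 16, 2)),
                  caseIds = c("a", "b"), sliceIdx = c(1L, 1L))
  res <- optimizeThreshold(list(t1, t2), valData, gridStep = 0.01)
  expect_equal(nrow(res$grid), 99)
  expect_equal(res$threshold, 0.01)
  expect_equal(res$criterionValue, 1)
  # graded map: Dice-optimal cut recovered, self-consistency of the score
  p <- t1 * 0.9 + 0.05
  res2 <- optimizeThreshold(list(p, t2 * 0.9 + 0.05), valData, 0.05)
  expect_true(all(abs(res2$grid$threshold -
                        seq(0.05, 0.95, by = 0.05)) < 1e-9))
  recheck <- mean(c(diceCoef(largestComponent(binarize(p, res2$threshold)),
                             t1),
                    diceCoef(largestComponent(binarize(t2 * 0.9 + 0.05,
                                                       res2$threshold)),
                             t2)))
  expect_equal(res2$criterionValue, recheck, tolerance = 1e-12)
  expect_equal(res2$criterionValue, 1)
  expect_error(optimizeThreshold(list(), list(images = array(0, c(4, 4, 0))),
                                 0.1), "empty")
})
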