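test_that("Dice overlap matches its definition and conventions", {
  X <- matrix(0, 5, 5); X[1, 1:4] <- 1           # |X| = 4
  Y <- matrix(0, 5, 5); Y[1, 2:5] <- 1; Y[2, 1:3] <- 1  # |Y| = 7
  Y[2, 1] <- 0                                    # |Y| = 6, overlap = 3
  expect_equal(sum(X), 4); expect_equal(sum(Y), 6)
  expect_equal(sum(X * Y), 3)
  expect_equal(diceCoef(X, Y), 0.6)
  expect_equal(diceCoef(Y, X), 0.6)
  expect_equal(diceCoef(X, X), 1)
  disj <- matrix(0, 5, 5); disj[5, 5] <- 1
  expect_equal(diceCoef(X, disj), 0)
  empty <- matrix(0, 5, 5)
  expect_equal(diceCoef(empty, empty), 1)   # agreement on absence
  expect_equal(diceCoef(X, empty), 0)
  expect_error(diceCoef(X, matrix(0, 3, 3)), "shape")
  # nesting monotonicity: a mask agrees better with a superset containing it
  sup <- X; sup[2, 1:2] <- 1
  expect_gte(diceCoef(sup, sup), diceCoef(X, sup))
})

test_that("boundary extraction yields closed physical-space contours", {
  m <- matrix(0, 30, 30); m[10:19, 12:21] <- 1   # 10 x 10 square
  cs <- extractBoundary(m, c(1, 1))
  expect_length(cs, 1)
  ct <- cs[[1]]
  expect_true(ct$closed)
  pts <- ct$points
  per <- sum(sqrt(rowSums((pts - pts[c(2:nrow(pts), 1), ])^2)))
  expect_lt(abs(per - 40), 2)
  expect_length(extractBoundary(matrix(0, 5, 5)), 0)
  # translation equivariance
  m2 <- matrix(0, 30, 30); m2[15:24, 12:21] <- 1
  c2 <- extractBoundary(m2, c(1, 1))[[1]]
  shifted <- ct$points; shifted[, 1] <- shifted[, 1] + 5
  expect_equal(sort(c2$points[, 1]), sort(shifted[, 1]), tolerance = 1e-9)
  expect_equal(hausdorffDist(c2$points, shifted), 0, tolerance = 1e-9)
  # two blobs: ordered by enclosed area, descending
  m3 <- m; m3[25:27, 2:4] <- 1
  cs3 <- extractBoundary(m3, c(1, 1))
  expect_length(cs3, 2)
  expect_gt(cs3[[1]]$area, cs3[[2]]$area)
  # anisotropic spacing scales the points
  ca <- extractBoundary(m, c(0.5, 2))[[1]]
  expect_lt(max(ca$points[, 1]), max(ct$points[, 1]))
})

test_that("Hausdorff distance equals the all-pairs brute-force oracle", {
  sq <- extractBoundary({m <- matrix(0, 20, 20); m[5:14, 5:14] <- 1; m},
                        c(1, 1))[[1]]$points
  expect_equal(hausdorffDist(sq, sq), 0)
  shifted <- sq; shifted[, 1] <- shifted[, 1] + 3
  expect_equal(hausdorffDist(sq, shifted), hausdorffOracle(sq, shifted),
               tolerance = 1e-12)
  for (seed in 1:25) {
    A <- randomContour(sample(20:200, 1), seed)
    B <- randomContour(sample(20:200, 1), seed + 1000)
    h <- hausdorffDist(A, B)
    expect_equal(h, hausdorffOracle(A, B), tolerance = 1e-12)
    expect_equal(h, hausdorffDist(B, A), tolerance = 1e-12)
  }
})

test_that("discrete Frechet distance matches the recursive-definition oracle",
{
  P <- cbind(c(0, 1), c(0, 0))
  Q <- cbind(c(0, 1), c(1, 1))
  expect_equal(frechetDist(P, Q), 1)
  expect_equal(frechetDist(P, P), 0)
  for (seed in 1:25) {
    n1 <- sample(5:40, 1); n2 <- sample(5:40, 1)
    A <- randomContour(n1, seed + 2000)
    B <- randomContour(n2, seed + 3000)
    expect_equal(frechetDist(A, B), frechetOracle(A, B), tolerance = 1e-12)
  }
})

test_that("Frechet dominates Hausdorff and both are rigid-motion invariant", {
  for (seed in 1:15) {
    A <- randomContour(sample(10:120, 1), seed + 4000)
    B <- randomContour(sample(10:120, 1), seed + 5000)
    fd <- frechetDist(A, B); hd <- hausdorffDist(A, B)
    expect_gte(fd + 1e-12, hd)
    th <- withr::with_seed(seed, runif(1, 0, 2 * pi))
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    shift <- c(3.2, -1.7)
    At <- sweep(A %*% R, 2, shift, `+`); Bt <- sweep(B %*% R, 2, shift, `+`)
    expect_equal(hausdorffDist(At, Bt), hd, tolerance = 1e-9)
    expect_equal(frechetDist(At, Bt), fd, tolerance = 1e-9)
  }
  # closed-contour start-shift handling: rotating the start index is free
  m <- matrix(0, 24, 24); m[6:17, 7:18] <- 1
  ct <- extractBoundary(m, c(1, 1))[[1]]
  rolled <- ct
  n <- nrow(ct$points)
  rolled$points <- ct$points[c(10:n, 1:9), ]
  expect_lt(frechetDist(ct, rolled, exactShifts = TRUE), 1e-9)
})

test_that("case evaluation aggregates slices pseudo-volumetrically", {
  ref <- array(0, c(32, 32, 4))
  for (k in 1:4) ref[10:20, 10:20, k] <- 1
  rec <- evaluateCase(ref, ref, c(0.781, 0.781, 4), "wall", "self")
  expect_equal(rec$dice, 1)
  expect_equal(rec$hausdorff, 0)
  expect_equal(rec$frechet, 0)
  expect_equal(rec$n_slices_evaluated, 4)
  # one-voxel in-plane dilation: HD equals the in-plane spacing
  pred <- array(0, c(32, 32, 4))
  for (k in 1:4) {
    d <- EBImage::dilate(ref[, , k], EBImage::makeBrush(3, "diamond"))
    pred[, , k] <- (d > 0) * 1
  }
  rec2 <- evaluateCase(pred, ref, c(0.781, 0.781, 4), "wall", "dil")
  expect_lt(rec2$dice, 1)
  expect_equal(rec2$hausdorff, 0.781, tolerance = 0.15)
  expect_gte(rec2$frechet, rec2$hausdorff - 1e-9)
  # slices with one empty side are excluded from distances, kept in Dice
  half <- ref; half[, , 3:4] <- 0
  rec3 <- evaluateCase(half, ref, c(1, 1, 4), "wall", "half")
  expect_equal(rec3$n_slices_evaluated, 2)
  expect_equal(rec3$dice, 2 * sum(half) / (sum(half) + sum(ref)))
  expect_error(evaluateCase(ref, array(0, c(16, 16, 2))), "grid")
})

test_that("cohort evaluation returns one record per case", {
  refs <- list(a = array(1, c(8, 8, 2)), b = array(1, c(8, 8, 2)))
  preds <- refs
  recs <- evaluateCohort(preds, refs, c(1, 1, 1), "lumen")
  expect_equal(nrow(recs), 2)
  expect_equal(recs$case_id, c("a", "b"))
  expect_true(all(recs$dice == 1))
})
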