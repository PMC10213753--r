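#' Training configuration
#'
#' The default recipe: Adam (learning rate 0.003), Dice loss, 50 epochs,
#' batch size 16, on-the-fly augmentation with vertical flips (probability
#' 0.5) and rotations uniform in \[-30, 30\] degrees.
#'
#' @param epochs number of epochs, >= 1.
#' @param batchSize mini-batch size, >= 1.
#' @param learningRate Adam step size, > 0.
#' @param optimizer only "adam".
#' @param loss only "dice".
#' @param augFlipProb vertical-flip probability.
#' @param augRotRange numeric(2) rotation range in degrees, within
#'   \[-180, 180\].
#' @param seed integer seed controlling shuffling, augmentation and dropout.
#' @param region one of "wall" (filled region inside the outer rectal wall
#'   boundary, i.e. lumen + wall), "lumen", "fat", "wall_annulus" (the wall
#'   ring alone) or "multiclass".
#' @return a list of class `TrainConfig`.
#' @export
trainConfig <- function(epochs = 50L, batchSize = 16L, learningRate = 0.003,
                        optimizer = "adam", loss = "dice",
                        augFlipProb = 0.5, augRotRange = c(-30, 30),
                        seed = 1L, region = "wall") {
  assertThat(epochs >= 1, "epochs must be >= 1")
  assertThat(batchSize >= 1, "batchSize must be >= 1")
  assertThat(learningRate > 0, "learningRate must be > 0")
  assertThat(identical(optimizer, "adam"), "only the adam optimizer exists")
  assertThat(identical(loss, "dice"), "only the dice loss exists")
  assertThat(all(abs(augRotRange) <= 180) && augRotRange[1] <= augRotRange[2],
             "rotation range must lie within [-180, 180]")
  assertThat(region %in% c("wall", "lumen", "fat", "wall_annulus",
                           "multiclass"), "unknown region tag")
  structure(list(epochs = as.integer(epochs), batchSize = as.integer(batchSize),
                 learningRate = learningRate, optimizer = optimizer,
                 loss = loss, augFlipProb = augFlipProb,
                 augRotRange = augRotRange, seed = as.integer(seed),
                 region = region), class = "TrainConfig")
}

#' Build the binary target mask for one region-specific task
#'
#' The wall model segments the filled region enclosed by the outer rectal
#' wall boundary (labels lumen + wall); the lumen model the lumen; the fat
#' model the perirectal fat. The wall annulus alone is available as
#' "wall_annulus". Muscle and background never appear in any target.
#'
#' @param labels 2D integer slice with values in 0..4.
#' @param region "wall", "lumen", "fat" or "wall_annulus".
#' @return binary 0/1 matrix with attribute `"region"`.
#' @export
makeRegionTarget <- function(labels, region) {
  assertThat(all(labels %in% 0:4), "labels must take values in {0..4}")
  mask <- switch(region,
                 wall = labels %in% c(1L, 2L),
                 lumen = labels == 1L,
                 fat = labels == 3L,
                 wall_annulus = labels == 2L,
                 stop("unknown region tag: ", region, call. = FALSE))
  out <- matrix(as.numeric(mask), nrow(labels), ncol(labels))
  attr(out, "region") <- region
  out
}

#' Soft Dice loss
#'
#' `1 - (2 * sum(p * t) + eps) / (sum(p) + sum(t) + eps)` for a binary task;
#' for a multiclass (softmax) prediction the per-class soft Dice is averaged
#' over the non-background classes. Differentiable in the prediction and
#' bounded in \[0, 1\].
#'
#' @param pred probabilities: 2D array (binary) or H x W x K (softmax), or a
#'   [ProbabilityMap-class].
#' @param target binary mask matching `pred` (binary case), or either an
#'   integer label image in 0..K-1 or a one-hot H x W x K array (multiclass).
#' @param eps smoothing constant.
#' @return scalar loss.
#' @export
diceLoss <- function(pred, target, eps = 1e-6) {
  if (is(pred, "ProbabilityMap")) pred <- pred@values
  if (length(dim(pred)) == 3) {
    K <- dim(pred)[3]
    if (length(dim(target)) == 2)
      target <- .oneHot(target, K)
    assertThat(identical(dim(pred), dim(target)), "shape mismatch")
    losses <- vapply(2:K, function(k)
      .softDice(pred[, , k], target[, , k], eps), numeric(1))
    mean(losses)
  } else {
    assertThat(identical(dim(pred), dim(target)), "shape mismatch")
    .softDice(pred, target, eps)
  }
}

.softDice <- function(p, t, eps) {
  1 - (2 * sum(p * t) + eps) / (sum(p) + sum(t) + eps)
}

.oneHot <- function(labels, K) {
  out <- array(0, c(dim(labels), K))
  for (k in seq_len(K)) out[, , k] <- (labels == k - 1) * 1
  out
}

# Batch soft-Dice loss and its gradient wrt the probabilities.
# probs: (H, W, K, N); targets: (H, W, K, N) one-hot or (H, W, 1, N) binary.
# For K > 1 the background channel (k = 1) is excluded from the average.
.diceLossBatch <- function(probs, targets, eps = 1e-6) {
  d <- dim(probs)
  K <- d[3]; N <- d[4]
  ks <- if (K > 1) 2:K else 1
  dprobs <- array(0, d)
  total <- 0
  for (n in seq_len(N)) {
    for (k in ks) {
      p <- probs[, , k, n]; t <- targets[, , k, n]
      S <- sum(p) + sum(t) + eps
      Tt <- 2 * sum(p * t) + eps
      total <- total + (1 - Tt / S)
      dprobs[, , k, n] <- -(2 * t * S - Tt) / S^2 / (N * length(ks))
    }
  }
  list(loss = total / (N * length(ks)), dprobs = dprobs)
}

#' Jointly augment an image/mask slice pair
#'
#' Draws one augmentation from the current RNG stream (or from `seed` when
#' given): a vertical flip (row reversal) with probability `flipProb`, then
#' a rotation with angle uniform on `rotRange` (degrees). The identical
#' geometric transform is applied to both; the image is interpolated
#' bilinearly, the mask with nearest neighbor so it stays binary (or integer
#' for multiclass label slices).
#'
#' @param image 2D numeric slice.
#' @param mask 2D mask slice of the same shape.
#' @param flipProb probability of the vertical flip.
#' @param rotRange numeric(2) rotation range in degrees.
#' @param seed optional integer seed for a reproducible standalone draw.
#' @return list with `image` and `mask`.
#' @export
augmentPair <- function(image, mask, flipProb = 0.5, rotRange = c(-30, 30),
                        seed = NULL) {
  assertThat(identical(dim(image), dim(mask)),
             "image and mask must share shape")
  doOne <- function() {
    if (runif(1) < flipProb) {
      image <- image[nrow(image):1, , drop = FALSE]
      mask <- mask[nrow(mask):1, , drop = FALSE]
    }
    angle <- runif(1, rotRange[1], rotRange[2])
    if (angle != 0) {
      image <- .rotateSlice(image, angle, nearest = FALSE)
      mask <- .rotateSlice(mask, angle, nearest = TRUE)
    }
    list(image = image, mask = mask)
  }
  if (is.null(seed)) doOne() else withSeed(seed, doOne())
}

# center rotation via EBImage, output geometry unchanged
.rotateSlice <- function(x, angle, nearest) {
  isInt <- is.integer(x)
  r <- EBImage::rotate(x * 1, angle,
                       filter = if (nearest) "none" else "bilinear",
                       output.dim = dim(x), bg.col = 0)
  out <- EBImage::imageData(r)
  if (nearest) out <- round(out)
  if (isInt) storage.mode(out) <- "integer"
  out
}

#' Assemble a slice dataset from preprocessed cases
#'
#' Runs [centerCropResize()] on every slice of every case, pairing the image
#' slice with its region target (or the multiclass label slice). Slices with
#' empty targets are kept: a region can be genuinely absent on end slices.
#'
#' @param prepCases list of preprocessed cases (as from [preprocessCase()]).
#' @param region region tag as in [trainConfig()].
#' @param config a [preprocessConfig()].
#' @return list with `images` (S x S x n), `targets` (S x S x n; binary, or
#'   integer class labels 0..3 when `region = "multiclass"`), `caseIds`,
#'   `sliceIdx` and per-slice crop `mappings`.
#' @export
makeSliceDataset <- function(prepCases, region, config = preprocessConfig()) {
  imgs <- list(); tgts <- list(); caseIds <- character(); sliceIdx <- integer()
  mappings <- list()
  for (ci in seq_along(prepCases)) {
    pc <- prepCases[[ci]]
    id <- names(prepCases)[ci] %||% as.character(ci)
    nz <- dim(pc$image)[3]
    for (k in seq_len(nz)) {
      img <- centerCropResize(pc$image[, , k], config, isMask = FALSE)
      lab <- pc$labels[, , k]
      tgt <- if (region == "multiclass") {
        ml <- lab
        ml[ml == 4L] <- 0L  # muscle folds into background for the softmax
        centerCropResize(ml, config, isMask = TRUE)
      } else {
        centerCropResize(makeRegionTarget(lab, region), config, isMask = TRUE)
      }
      mappings[[length(mappings) + 1L]] <- attr(img, "cropMapping")
      attr(img, "cropMapping") <- NULL
      attr(tgt, "cropMapping") <- NULL
      imgs[[length(imgs) + 1L]] <- img
      tgts[[length(tgts) + 1L]] <- tgt
      caseIds <- c(caseIds, id)
      sliceIdx <- c(sliceIdx, k)
    }
  }
  list(images = simplify2array(imgs), targets = simplify2array(tgts),
       caseIds = caseIds, sliceIdx = sliceIdx, mappings = mappings,
       region = region)
}

# stack a set of slice indices into network batch tensors
.assembleBatch <- function(ds, idx, cfg, train, flipProb, rotRange) {
  S <- dim(ds$images)[1]
  K <- if (cfg$head == "softmax_multiclass") cfg$nClasses else 1L
  x <- array(0, c(S, S, 1L, length(idx)))
  t <- array(0, c(S, S, K, length(idx)))
  for (j in seq_along(idx)) {
    img <- ds$images[, , idx[j]]
    msk <- ds$targets[, , idx[j]]
    if (train) {
      aug <- augmentPair(img, msk, flipProb, rotRange)
      img <- aug$image; msk <- aug$mask
    }
    x[, , 1, j] <- img
    if (K > 1) t[, , , j] <- .oneHot(msk, K) else t[, , 1, j] <- msk
  }
  list(x = x, t = t)
}

#' Train a U-Net with the Dice-loss recipe
#'
#' Runs `epochs` passes of Adam over shuffled mini-batches, each slice
#' augmented on the fly, minimizing the soft Dice loss; records per-epoch
#' training and validation loss. Deterministic for a fixed seed on a fixed
#' BLAS/thread configuration. The final-epoch weights are returned.
#'
#' @param model an untrained (or resumed) [UNetModel-class].
#' @param trainData slice dataset from [makeSliceDataset()].
#' @param valData optional validation slice dataset.
#' @param config a [trainConfig()].
#' @param verbose print per-epoch losses?
#' @return list with `model` (trained [UNetModel-class]) and `history`
#'   (data.frame epoch / train_loss / val_loss).
#' @export
trainModel <- function(model, trainData, valData = NULL,
                       config = trainConfig(), verbose = FALSE) {
  n <- dim(trainData$images)[3]
  assertThat(n >= 1, "empty training set")
  cfg <- model@config
  params <- model@params
  state <- model@state
  adamM <- lapply(params, function(p) p * 0)
  adamV <- adamM
  b1 <- 0.9; b2 <- 0.999; adamEps <- 1e-8; step <- 0
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  withSeed(config$seed, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      epochLoss <- 0; nb <- 0
      for (start in seq(1, n, by = config$batchSize)) {
        idx <- ord[start:min(n, start + config$batchSize - 1)]
        mb <- .assembleBatch(trainData, idx, cfg, TRUE,
                             config$augFlipProb, config$augRotRange)
        mtmp <- new("UNetModel", config = cfg, params = params,
                    state = state, trained = FALSE)
        fw <- .unetForward(mtmp, mb$x, training = TRUE)
        state[names(fw$state)] <- fw$state
        dl <- .diceLossBatch(fw$probs, mb$t)
        if (!is.finite(dl$loss))
          stop("non-finite training loss at epoch ", ep, call. = FALSE)
        grads <- .unetBackward(mtmp, fw, dl$dprobs)
        step <- step + 1
        corr <- sqrt(1 - b2^step) / (1 - b1^step)
        for (nm in names(grads)) {
          g <- grads[[nm]]
          adamM[[nm]] <- b1 * adamM[[nm]] + (1 - b1) * g
          adamV[[nm]] <- b2 * adamV[[nm]] + (1 - b2) * g^2
          params[[nm]] <- params[[nm]] - config$learningRate * corr *
            adamM[[nm]] / (sqrt(adamV[[nm]]) + adamEps)
        }
        epochLoss <- epochLoss + dl$loss; nb <- nb + 1
      }
      valLoss <- NA_real_
      if (!is.null(valData)) {
        mval <- new("UNetModel", config = cfg, params = params,
                    state = state, trained = TRUE)
        valLoss <- .evalLoss(mval, valData, config$batchSize)
      }
      history <- rbind(history,
                       data.frame(epoch = ep, train_loss = epochLoss / nb,
                                  val_loss = valLoss))
      if (verbose)
        message(sprintf("epoch %d: train %.4f val %.4f", ep,
                        epochLoss / nb, valLoss))
    }
  })
  list(model = new("UNetModel", config = cfg, params = params, state = state,
                   trained = TRUE),
       history = history)
}

# mean eval-mode dice loss over a slice dataset
.evalLoss <- function(model, ds, batchSize) {
  n <- dim(ds$images)[3]
  tot <- 0; nb <- 0
  for (start in seq(1, n, by = batchSize)) {
    idx <- start:min(n, start + batchSize - 1)
    mb <- .assembleBatch(ds, idx, model@config, FALSE, 0, c(0, 0))
    fw <- .unetForward(model, mb$x, training = FALSE)
    tot <- tot + .diceLossBatch(fw$probs, mb$t)$loss
    nb <- nb + 1
  }
  tot / nb
}
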