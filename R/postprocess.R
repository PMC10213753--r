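#' Binarize a sigmoid probability map
#'
#' @param prob a sigmoid-head [ProbabilityMap-class] or 2D probability array.
#' @param threshold scalar in (0, 1); pixels with probability `>= threshold`
#'   become foreground.
#' @return binary 0/1 matrix.
#' @export
binarize <- function(prob, threshold) {
  if (is(prob, "ProbabilityMap")) {
    assertThat(prob@head == "sigmoid",
               "softmax maps must go through multiclassToMasks")
    prob <- prob@values
  }
  assertThat(threshold > 0 && threshold < 1, "threshold must lie in (0, 1)")
  (prob >= threshold) * 1
}

#' Convert a softmax probability map to per-region binary masks
#'
#' Per-pixel argmax over the channels, ties broken to the lowest channel
#' index. Emits one binary mask per non-background class; the masks are
#' mutually exclusive and, together with background, partition the image.
#'
#' @param prob a softmax-head [ProbabilityMap-class] or H x W x K array.
#' @param classNames optional names for the K-1 non-background masks.
#' @return named list of binary matrices.
#' @export
multiclassToMasks <- function(prob, classNames = NULL) {
  if (is(prob, "ProbabilityMap")) {
    assertThat(prob@head == "softmax", "need a softmax map")
    prob <- prob@values
  }
  assertThat(length(dim(prob)) == 3, "need an H x W x K array")
  K <- dim(prob)[3]
  arg <- apply(prob, c(1, 2), which.max)  # which.max: lowest-index ties
  masks <- lapply(2:K, function(k) (arg == k) * 1)
  names(masks) <- classNames %||% paste0("class", 2:K - 1)
  masks
}

#' Keep only the largest connected component of a binary mask
#'
#' Components are found at the requested connectivity (8 by default in 2D,
#' 26 available for 3D inputs); all but one component of maximal voxel count
#' are removed. Ties go to the component labeled first in column-major scan
#' order. Empty input passes through unchanged.
#'
#' @param mask 2D or 3D binary array.
#' @param connectivity 4 or 8 (2D), 6 or 26 (3D).
#' @return binary array of the same shape with at most one component.
#' @export
largestComponent <- function(mask, connectivity = if (length(dim(mask)) == 2)
  8L else 26L) {
  d <- dim(mask)
  lab <- .labelComponents(as.logical(mask > 0), as.integer(d),
                          as.integer(connectivity))
  ncomp <- attr(lab, "ncomp")
  if (ncomp <= 1) return((mask > 0) * 1)
  sizes <- tabulate(lab, nbins = ncomp)
  keep <- which.max(sizes)  # first maximal = smallest label index
  out <- (lab == keep) * 1
  dim(out) <- d
  out
}

#' Optimize the binarization threshold on a validation set
#'
#' Evaluates the deployed post-processing pipeline (binarize at the
#' candidate threshold, then largest-connected-component per slice) against
#' the validation targets on the grid `{step, 2*step, ..., 1-step}`,
#' scoring each threshold by the mean per-case pseudo-volumetric Dice.
#' Returns the argmax, ties broken to the smallest threshold.
#'
#' @param model a trained sigmoid-head [UNetModel-class], or a list of
#'   precomputed per-slice probability arrays aligned with `valData` (useful
#'   for testing the search itself).
#' @param valData validation slice dataset from [makeSliceDataset()].
#' @param gridStep grid spacing in (0, 0.5].
#' @return list of class `ThresholdResult` with `threshold`,
#'   `criterionValue` and the evaluated `grid` (data.frame threshold/score).
#' @export
optimizeThreshold <- function(model, valData, gridStep = 0.01) {
  n <- dim(valData$images)[3]
  assertThat(n >= 1, "empty validation set")
  assertThat(gridStep > 0 && gridStep <= 0.5, "gridStep must be in (0, 0.5]")
  pv <- if (is(model, "UNetModel")) {
    lapply(predictSlices(model, valData$images), probValues)
  } else {
    assertThat(is.list(model) && length(model) == n,
               "need a UNetModel or one probability map per slice")
    model
  }
  thresholds <- seq(gridStep, 1 - gridStep + 1e-12, by = gridStep)
  thresholds <- thresholds[thresholds < 1]
  caseIds <- unique(valData$caseIds)
  scores <- vapply(thresholds, function(th) {
    perCase <- vapply(caseIds, function(id) {
      sel <- which(valData$caseIds == id)
      pred <- lapply(sel, function(s)
        largestComponent(binarize(pv[[s]], th)))
      predVol <- simplify2array(pred)
      refVol <- valData$targets[, , sel, drop = FALSE]
      diceCoef(predVol, refVol)
    }, numeric(1))
    mean(perCase)
  }, numeric(1))
  best <- which.max(scores)  # which.max: smallest threshold on ties
  structure(list(threshold = thresholds[best],
                 criterionValue = scores[best],
                 grid = data.frame(threshold = thresholds, score = scores)),
            class = "ThresholdResult")
}
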