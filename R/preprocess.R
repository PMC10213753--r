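#' Preprocessing configuration
#'
#' Settings for the harmonization chain applied to every scan, in fixed
#' order: resample to a common spacing, bias-field correction,
#' reference-muscle intensity normalization, then center-crop/resize of each
#' slice to the network input size.
#'
#' @param targetSpacing numeric(3) mm; the common resolution all volumes are
#'   resampled to (default 0.781 x 0.781 x 4 mm).
#' @param biasMethod "smooth_div" (self-contained smooth-divisor correction),
#'   "n4" (delegates to an external N4 implementation, see
#'   [correctBiasField()]) or "none".
#' @param biasParams list of method-specific settings; for "smooth_div",
#'   `kernelFraction` is the Gaussian sigma as a fraction of the in-plane
#'   extent (default 0.5; large enough that anatomy barely leaks into the
#'   divisor while the smooth bias trend is still captured).
#' @param cropFraction fraction of each in-plane axis retained around the
#'   image center, in (0, 1].
#' @param netInputSize network input side length in pixels (>= 16).
#' @return a validated list of class `PreprocessConfig`.
#' @export
preprocessConfig <- function(targetSpacing = c(0.781, 0.781, 4.0),
                             biasMethod = "smooth_div",
                             biasParams = list(kernelFraction = 0.5),
                             cropFraction = 0.5,
                             netInputSize = 128L) {
  assertThat(all(targetSpacing > 0), "targetSpacing must be positive")
  assertThat(biasMethod %in% c("n4", "smooth_div", "none"),
             "biasMethod must be one of n4, smooth_div, none")
  assertThat(cropFraction > 0 && cropFraction <= 1,
             "cropFraction must lie in (0, 1]")
  assertThat(netInputSize >= 16, "netInputSize must be >= 16")
  structure(list(targetSpacing = as.numeric(targetSpacing),
                 biasMethod = biasMethod, biasParams = biasParams,
                 cropFraction = cropFraction,
                 netInputSize = as.integer(netInputSize)),
            class = "PreprocessConfig")
}

# 1D resampling operator from a source axis (n voxels at spacing s) to the
# target spacing t; linear or nearest weights, positions = index * spacing.
.resampleMatrix <- function(n, s, t, interp) {
  nOut <- as.integer(round((n - 1) * s / t)) + 1L
  if (nOut < 2) stop("resampled axis would have < 2 voxels", call. = FALSE)
  coord <- (seq_len(nOut) - 1) * t / s          # 0-based source coordinate
  coord <- pmin(pmax(coord, 0), n - 1)
  M <- matrix(0, nOut, n)
  if (interp == "nearest") {
    M[cbind(seq_len(nOut), as.integer(round(coord)) + 1L)] <- 1
  } else {
    i0 <- pmin(floor(coord), n - 2)
    w <- coord - i0
    M[cbind(seq_len(nOut), i0 + 1L)] <- 1 - w
    M[cbind(seq_len(nOut), i0 + 2L)] <- M[cbind(seq_len(nOut), i0 + 2L)] + w
  }
  M
}

#' Resample a volume to a target voxel spacing
#'
#' Trilinear (images) or nearest-neighbor (label volumes) resampling on the
#' package's 0-based `position = index * spacing` grid convention; physical
#' extent is preserved to within one output voxel per axis.
#'
#' @param volume 3D array.
#' @param spacing numeric(3) current spacing, mm.
#' @param targetSpacing numeric(3) requested spacing, mm.
#' @param interp "linear" or "nearest".
#' @return list with `data` (resampled array) and `spacing`.
#' @export
resampleToSpacing <- function(volume, spacing, targetSpacing,
                              interp = c("linear", "nearest")) {
  interp <- match.arg(interp)
  assertThat(all(spacing > 0) && all(targetSpacing > 0),
             "spacings must be strictly positive")
  d <- dim(volume)
  isInt <- is.integer(volume)
  out <- volume * 1
  for (ax in 1:3) {
    if (isTRUE(all.equal(spacing[ax], targetSpacing[ax]))) next
    M <- .resampleMatrix(d[ax], spacing[ax], targetSpacing[ax], interp)
    out <- applyAlongAxis(out, M, ax)
  }
  if (isInt) out <- array(as.integer(round(out)), dim(out))
  list(data = out, spacing = as.numeric(targetSpacing))
}

#' Suppress the smooth multiplicative intensity trend of a volume
#'
#' `smooth_div` divides the volume by a heavily Gaussian-smoothed copy of
#' itself (sigma = `kernelFraction` of the in-plane extent, default one
#' half) and rescales to
#' preserve the global mean; it is the self-contained default. `n4` shells
#' out to the N4 algorithm of an installed SimpleITK (via `python`), the
#' higher-fidelity option. `none` is the identity.
#'
#' @param volume 3D array, strictly positive where tissue exists.
#' @param config a [preprocessConfig()].
#' @param spacing numeric(3) mm, used to size the smoothing kernel.
#' @return corrected volume of the same shape.
#' @export
correctBiasField <- function(volume, config = preprocessConfig(),
                             spacing = c(1, 1, 1)) {
  method <- config$biasMethod
  if (method == "none") return(volume)
  if (method == "smooth_div") {
    frac <- config$biasParams$kernelFraction %||% 0.5
    d <- dim(volume)
    extent <- (d[1:2] - 1) * spacing[1:2]
    sigmaMm <- c(rep(min(extent) * frac, 2), (d[3] - 1) * spacing[3] * frac)
    div <- gaussSmooth3d(volume, sigmaMm / spacing)
    assertThat(min(div) > 0,
               "smooth_div requires a positive smoothed volume")
    out <- volume / div
    return(out * (mean(volume) / mean(out)))
  }
  # n4: delegate to SimpleITK through the system python, if present
  assertThat(min(volume) > 0, "n4 requires strictly positive intensities")
  py <- Sys.which("python")
  if (!nzchar(py))
    stop("method 'n4' needs a python with SimpleITK; use 'smooth_div'",
         call. = FALSE)
  tin <- tempfile(fileext = ".nii"); tout <- tempfile(fileext = ".nii")
  writeVolume(volume, spacing, tin)
  script <- sprintf(paste0(
    "import SimpleITK as sitk\n",
    "img = sitk.ReadImage(%s, sitk.sitkFloat64)\n",
    "out = sitk.N4BiasFieldCorrection(img)\n",
    "sitk.WriteImage(out, %s)\n"), shQuote(tin), shQuote(tout))
  sf <- tempfile(fileext = ".py"); writeLines(script, sf)
  status <- system2(py, sf, stdout = FALSE, stderr = FALSE)
  if (status != 0 || !file.exists(tout))
    stop("N4 delegation failed; use biasMethod = 'smooth_div'", call. = FALSE)
  readVolume(tout)$data
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalize a volume by its mean intensity over a reference-muscle mask
#'
#' Divides the whole volume by the mean intensity inside the (3D) muscle
#' mask, so the muscle mean of the output is exactly 1. This removes
#' institution-scale intensity differences.
#'
#' @param volume 3D array.
#' @param muscleMask 3D logical/0-1 array of the same shape, nonempty.
#' @return normalized volume.
#' @export
normalizeByMuscle <- function(volume, muscleMask) {
  assertThat(identical(dim(volume), dim(muscleMask)),
             "volume and muscleMask must share shape")
  assertThat(any(muscleMask > 0), "muscle mask is empty")
  m <- mean(volume[muscleMask > 0])
  assertThat(is.finite(m) && m > 0, "muscle mean must be positive")
  volume / m
}

#' Center-crop a slice and resize it to the network input size
#'
#' Retains the central `cropFraction` of each in-plane axis and resizes to
#' `netInputSize` squared using pixel-center-aligned linear interpolation
#' (images) or nearest neighbor (masks, which therefore keep only values
#' present in the input). The affine crop geometry is recorded in the
#' `"cropMapping"` attribute so predictions can be mapped back with
#' [uncropPrediction()].
#'
#' @param slice 2D array.
#' @param config a [preprocessConfig()].
#' @param isMask logical; nearest-neighbor resize when TRUE.
#' @return `netInputSize` x `netInputSize` array with attribute
#'   `"cropMapping"`.
#' @export
centerCropResize <- function(slice, config = preprocessConfig(),
                             isMask = FALSE) {
  d <- dim(slice)
  w <- as.integer(round(d * config$cropFraction))
  assertThat(all(w >= 2), "crop window smaller than 2 x 2")
  r0 <- floor((d - w) / 2) + 1L
  win <- slice[r0[1]:(r0[1] + w[1] - 1L), r0[2]:(r0[2] + w[2] - 1L),
               drop = FALSE]
  size <- config$netInputSize
  out <- .resizeBilinear(win, c(size, size),
                         nearest = isMask)
  if (isMask) storage.mode(out) <- storage.mode(slice)
  attr(out, "cropMapping") <- list(origShape = d, start = r0, window = w,
                                   size = size)
  out
}

# pixel-center-aligned 1D resize operator from n to m samples
.resizeMatrix <- function(n, m, nearest) {
  coord <- ((seq_len(m) - 0.5) * n / m) + 0.5 - 1  # 0-based source coord
  coord <- pmin(pmax(coord, 0), n - 1)
  M <- matrix(0, m, n)
  if (nearest) {
    M[cbind(seq_len(m), as.integer(round(coord)) + 1L)] <- 1
  } else {
    i0 <- pmin(floor(coord), max(n - 2, 0))
    wgt <- coord - i0
    M[cbind(seq_len(m), i0 + 1L)] <- 1 - wgt
    if (n >= 2) M[cbind(seq_len(m), i0 + 2L)] <-
        M[cbind(seq_len(m), i0 + 2L)] + wgt
  }
  M
}

.resizeBilinear <- function(x, newDim, nearest = FALSE) {
  out <- .resizeMatrix(nrow(x), newDim[1], nearest) %*% (x * 1)
  t(.resizeMatrix(ncol(x), newDim[2], nearest) %*% t(out))
}

#' Map a network-grid prediction back to the pre-crop slice grid
#'
#' Inverts the geometry recorded by [centerCropResize()]: the prediction is
#' resized back to the crop window (linear interpolation; masks are
#' re-thresholded at 0.5 to stay binary) and embedded at the window position,
#' zeros elsewhere.
#'
#' @param pred 2D array on the network grid.
#' @param mapping the `"cropMapping"` attribute produced by
#'   [centerCropResize()].
#' @param isMask logical; threshold the result at 0.5 when TRUE.
#' @return 2D array on the original pre-crop grid.
#' @export
uncropPrediction <- function(pred, mapping, isMask = FALSE) {
  assertThat(is.list(mapping) && !is.null(mapping$origShape),
             "mapping must come from centerCropResize")
  assertThat(all(dim(pred) == mapping$size),
             "prediction shape does not match the recorded geometry")
  win <- .resizeBilinear(pred, mapping$window)
  if (isMask) win <- (win >= 0.5) * 1
  out <- array(0, mapping$origShape)
  r0 <- mapping$start; w <- mapping$window
  out[r0[1]:(r0[1] + w[1] - 1L), r0[2]:(r0[2] + w[2] - 1L)] <- win
  out
}

#' Run the full harmonization chain on one phantom case
#'
#' Fixed order: resample (linear image / nearest labels) to the target
#' spacing, bias-field correction, muscle normalization. The crop/resize to
#' the network grid is applied later, slice-wise, when datasets are
#' assembled, so that evaluation can run on this pre-crop grid.
#'
#' @param case a [PhantomCase-class].
#' @param config a [preprocessConfig()].
#' @return list with `image`, `labels`, `spacing` on the resampled grid.
#' @export
preprocessCase <- function(case, config = preprocessConfig()) {
  img <- resampleToSpacing(case@image, case@spacing, config$targetSpacing,
                           "linear")
  lab <- resampleToSpacing(case@labels, case@spacing, config$targetSpacing,
                           "nearest")
  vol <- correctBiasField(img$data, config, spacing = img$spacing)
  vol <- normalizeByMuscle(vol, lab$data == 4L)
  list(image = vol, labels = lab$data, spacing = img$spacing)
}
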