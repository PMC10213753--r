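#' PhantomSpec: parameters of the synthetic rectal-phantom generator
#'
#' Describes the geometry, contrast and corruption model of a synthetic
#' "rectal MRI" cohort: nested lumen/wall/perirectal-fat ring anatomy placed
#' at the grid center, a separate reference-muscle disk, a smooth
#' multiplicative bias field, additive Gaussian noise, and bright-lumen
#' ("rectal gel") versus dark-lumen contrast regimes.
#'
#' @slot gridShape integer(3); voxels per axis (rows, cols, slices).
#' @slot voxelSpacing numeric(3); mm per axis.
#' @slot lumenRadiusRange numeric(2); lumen radius range, mm.
#' @slot wallThicknessRange numeric(2); rectal-wall thickness range, mm.
#' @slot fatRingThicknessRange numeric(2); perirectal fat ring thickness, mm.
#' @slot regionIntensities named numeric; mean gray level for background,
#'   lumen, wall, fat and muscle (arbitrary units, strictly positive).
#' @slot gelMode logical; TRUE gives a bright lumen (endorectal gel), FALSE
#'   puts the lumen within 10% of the wall intensity.
#' @slot noiseSigma numeric; additive noise SD as a fraction of the wall
#'   intensity.
#' @slot biasAmplitude numeric in [0,1); peak multiplicative deviation of the
#'   bias field from 1.
#' @slot biasSmoothness numeric; correlation length of the bias field, mm.
#' @slot deformMagnitude numeric; boundary perturbation scale, mm.
#' @slot muscleOffset numeric; displacement of the reference-muscle disk from
#'   the grid center, mm.
#' @slot muscleRadius numeric; radius of the reference-muscle disk, mm.
#' @slot qualityMode character; "standard" or "degraded" (doubled noise,
#'   halved wall/fat contrast).
#' @slot planeMode character; "axial_like" or "coronal_like" (in-plane
#'   elongation of the anatomy).
#' @slot anisotropyRange numeric(2); range of the in-plane elongation factor.
#' @exportClass PhantomSpec
setClass("PhantomSpec", representation(
  gridShape = "integer", voxelSpacing = "numeric",
  lumenRadiusRange = "numeric", wallThicknessRange = "numeric",
  fatRingThicknessRange = "numeric", regionIntensities = "numeric",
  gelMode = "logical", noiseSigma = "numeric", biasAmplitude = "numeric",
  biasSmoothness = "numeric", deformMagnitude = "numeric",
  muscleOffset = "numeric", muscleRadius = "numeric",
  qualityMode = "character", planeMode = "character",
  anisotropyRange = "numeric"))

setValidity("PhantomSpec", function(object) {
  msgs <- character()
  chk <- function(cond, m) if (!isTRUE(cond)) msgs <<- c(msgs, m)
  chk(length(object@gridShape) == 3 && all(object@gridShape[1:2] >= 16) &&
        object@gridShape[3] >= 2,
      "gridShape needs in-plane axes >= 16 voxels and >= 2 slices")
  chk(all(object@voxelSpacing > 0), "voxelSpacing must be strictly positive")
  for (nm in c("lumenRadiusRange", "wallThicknessRange",
               "fatRingThicknessRange")) {
    r <- slot(object, nm)
    chk(length(r) == 2 && all(r > 0) && r[1] <= r[2],
        paste(nm, "must be a positive increasing range"))
  }
  chk(all(c("background", "lumen", "wall", "fat", "muscle") %in%
            names(object@regionIntensities)) &&
        all(object@regionIntensities > 0),
      "regionIntensities must name all five regions with positive values")
  chk(object@noiseSigma >= 0, "noiseSigma must be >= 0")
  chk(object@biasAmplitude >= 0 && object@biasAmplitude < 1,
      "biasAmplitude must lie in [0, 1)")
  chk(object@qualityMode %in% c("standard", "degraded"),
      "qualityMode must be 'standard' or 'degraded'")
  chk(object@planeMode %in% c("axial_like", "coronal_like"),
      "planeMode must be 'axial_like' or 'coronal_like'")
  chk(length(object@anisotropyRange) == 2 && all(object@anisotropyRange > 0) &&
        object@anisotropyRange[1] <= object@anisotropyRange[2],
      "anisotropyRange must be a positive increasing range")
  # anatomy (with deformation and muscle disk) must fit the in-plane extent
  halfExtent <- min((object@gridShape[1:2] - 1) * object@voxelSpacing[1:2]) / 2
  rmax <- object@lumenRadiusRange[2] + object@wallThicknessRange[2] +
    object@fatRingThicknessRange[2] + object@deformMagnitude
  chk(rmax < halfExtent, "anatomy does not fit inside the grid extent")
  chk(object@muscleOffset + object@muscleRadius < halfExtent,
      "muscle disk does not fit inside the grid extent")
  chk(object@muscleOffset - object@muscleRadius > rmax,
      "muscle disk overlaps the rectal anatomy")
  if (length(msgs)) msgs else TRUE
})

#' PhantomCase: one synthetic scan with ground-truth labels
#'
#' Pairs a scalar image volume with an integer label volume (0 = background,
#' 1 = lumen, 2 = wall, 3 = perirectal fat, 4 = reference muscle) on a common
#' grid with shared voxel spacing. Stands in for one annotated patient scan.
#'
#' @slot image 3D numeric array, arbitrary intensity units.
#' @slot labels 3D integer array with values in 0..4.
#' @slot spacing numeric(3), mm per axis.
#' @slot specId character provenance tag.
#' @slot seed integer RNG seed the case was generated from.
#' @exportClass PhantomCase
setClass("PhantomCase", representation(
  image = "array", labels = "array", spacing = "numeric",
  specId = "character", seed = "integer"))

setValidity("PhantomCase", function(object) {
  msgs <- character()
  if (!identical(dim(object@image), dim(object@labels)))
    msgs <- c(msgs, "image and labels must share shape")
  if (!all(object@labels %in% 0:4))
    msgs <- c(msgs, "labels must take values in {0,1,2,3,4}")
  if (length(object@spacing) != 3 || any(object@spacing <= 0))
    msgs <- c(msgs, "spacing must be 3 positive values")
  if (length(msgs)) msgs else TRUE
})

#' ProbabilityMap: per-pixel network output before binarization
#'
#' @slot values 2D array (sigmoid head) or 3D array H x W x K (softmax head)
#'   of per-pixel probabilities.
#' @slot head character; "sigmoid" or "softmax".
#' @slot geometry list describing the slice geometry the map lives on
#'   (shape, spacing and, when cropped, the crop mapping).
#' @exportClass ProbabilityMap
setClass("ProbabilityMap", representation(
  values = "array", head = "character", geometry = "list"))

setValidity("ProbabilityMap", function(object) {
  v <- object@values
  if (any(v < -1e-8 | v > 1 + 1e-8)) return("probabilities must lie in [0,1]")
  if (object@head == "softmax") {
    if (length(dim(v)) != 3) return("softmax map must be H x W x K")
    s <- apply(v, c(1, 2), sum)
    if (max(abs(s - 1)) > 1e-5) return("softmax channels must sum to 1")
  } else if (object@head == "sigmoid") {
    if (length(dim(v)) != 2) return("sigmoid map must be 2D")
  } else return("head must be 'sigmoid' or 'softmax'")
  TRUE
})

#' UNetModel: a 2D U-Net model handle
#'
#' Holds the architecture configuration, the parameter tensors (convolution
#' weights stored as GEMM-ready matrices) and the batch-normalization running
#' statistics used at inference.
#'
#' @slot config list; see [unetConfig()].
#' @slot params named list of parameter arrays.
#' @slot state named list of batch-norm running means/variances.
#' @slot trained logical; TRUE after [trainModel()].
#' @exportClass UNetModel
setClass("UNetModel", representation(
  config = "list", params = "list", state = "list", trained = "logical"))

#' @describeIn PhantomCase-class image volume accessor
#' @param object,x a `PhantomCase`, `ProbabilityMap` or `UNetModel`
#' @export
setGeneric("imageData", function(x) standardGeneric("imageData"))
#' @rdname PhantomCase-class
#' @export
setGeneric("labelData", function(x) standardGeneric("labelData"))
#' @rdname PhantomCase-class
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))
#' @rdname ProbabilityMap-class
#' @export
setGeneric("probValues", function(x) standardGeneric("probValues"))
#' @rdname ProbabilityMap-class
#' @export
setGeneric("headType", function(x) standardGeneric("headType"))

#' @rdname PhantomCase-class
setMethod("imageData", "PhantomCase", function(x) x@image)
#' @rdname PhantomCase-class
setMethod("labelData", "PhantomCase", function(x) x@labels)
#' @rdname PhantomCase-class
setMethod("voxelSpacing", "PhantomCase", function(x) x@spacing)
#' @rdname ProbabilityMap-class
setMethod("probValues", "ProbabilityMap", function(x) x@values)
#' @rdname ProbabilityMap-class
setMethod("headType", "ProbabilityMap", function(x) x@head)

setMethod("show", "PhantomSpec", function(object) {
  cat("PhantomSpec:", paste(object@gridShape, collapse = " x "),
      "voxels @", paste(signif(object@voxelSpacing, 3), collapse = " x "),
      "mm\n")
  cat("  lumen", paste(object@lumenRadiusRange, collapse = "-"),
      "mm | wall", paste(object@wallThicknessRange, collapse = "-"),
      "mm | fat", paste(object@fatRingThicknessRange, collapse = "-"), "mm\n")
  cat("  gel:", object@gelMode, "| quality:", object@qualityMode,
      "| plane:", object@planeMode, "\n")
  cat("  noise", object@noiseSigma, "| bias", object@biasAmplitude,
      "| deform", object@deformMagnitude, "mm\n")
})

setMethod("show", "PhantomCase", function(object) {
  cat("PhantomCase", object@specId, "seed", object@seed, ":",
      paste(dim(object@image), collapse = " x "), "voxels\n")
  tab <- table(factor(object@labels, levels = 0:4))
  cat("  label voxels (bg/lumen/wall/fat/muscle):",
      paste(tab, collapse = "/"), "\n")
})

setMethod("show", "ProbabilityMap", function(object) {
  cat("ProbabilityMap (", object@head, " head): ",
      paste(dim(object@values), collapse = " x "), "\n", sep = "")
})

setMethod("show", "UNetModel", function(object) {
  cfg <- object@config
  cat("UNetModel:", cfg$inputSize, "x", cfg$inputSize, "input, depth",
      cfg$depth, ", base filters", cfg$baseFilters, ",", cfg$head, "head")
  if (cfg$head == "softmax_multiclass") cat(" (", cfg$nClasses, "classes )")
  cat("\n  parameters:", countParams(object),
      if (object@trained) "(trained)" else "(untrained)", "\n")
})
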