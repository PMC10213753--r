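#' Construct a synthetic rectal-phantom specification
#'
#' The phantom emulates the anatomy a rectal T2w MRI slice presents: a lumen
#' disk nested inside the rectal wall, nested inside a perirectal fat ring,
#' with a separate reference-muscle disk (the normalization reference), all
#' perturbed by low-order Fourier boundary deformation, a smooth
#' multiplicative bias field and additive Gaussian noise. Institution-like
#' contrast regimes are controlled by `gelMode` (bright vs. near-wall lumen),
#' `qualityMode` ("degraded" doubles the noise and halves the wall/fat
#' contrast) and `planeMode` ("coronal_like" elongates the anatomy along one
#' in-plane axis).
#'
#' @param gridShape integer(3) voxels per axis (rows, cols, slices).
#' @param voxelSpacing numeric(3) mm per axis.
#' @param lumenRadiusRange,wallThicknessRange,fatRingThicknessRange
#'   numeric(2) mm ranges the per-case geometry is drawn from.
#' @param regionIntensities named numeric mean gray levels; the lumen entry
#'   may be `NA` to derive it from `gelMode` (2.4x wall when gel is present,
#'   1.05x wall without gel).
#' @param gelMode logical; endorectal gel present (bright lumen)?
#' @param noiseSigma additive noise SD as a fraction of wall intensity.
#' @param biasAmplitude peak multiplicative bias deviation, in [0,1).
#' @param biasSmoothness bias-field correlation length, mm.
#' @param deformMagnitude boundary perturbation scale, mm.
#' @param muscleOffset,muscleRadius placement of the reference-muscle disk, mm.
#' @param qualityMode "standard" or "degraded".
#' @param planeMode "axial_like" or "coronal_like".
#' @param anisotropyRange numeric(2) range of the in-plane elongation factor
#'   of the anatomy; `NULL` derives it from `planeMode` (mild for axial,
#'   1.6-2.1 for coronal-like).
#' @return a validated [PhantomSpec-class] object.
#' @examples
#' spec <- phantomSpec(gridShape = c(64L, 64L, 6L),
#'                     lumenRadiusRange = c(3, 5.5),
#'                     wallThicknessRange = c(1.5, 2.5),
#'                     fatRingThicknessRange = c(3.5, 6),
#'                     muscleOffset = 19, muscleRadius = 3.5)
#' case <- generatePhantom(spec, seed = 1)
#' @export
phantomSpec <- function(gridShape = c(128L, 128L, 10L),
                        voxelSpacing = c(0.781, 0.781, 4.0),
                        lumenRadiusRange = c(4, 8),
                        wallThicknessRange = c(2, 4),
                        fatRingThicknessRange = c(5, 9),
                        regionIntensities = c(background = 30, lumen = NA,
                                              wall = 70, fat = 140,
                                              muscle = 100),
                        gelMode = TRUE,
                        noiseSigma = 0.08,
                        biasAmplitude = 0.2,
                        biasSmoothness = 40,
                        deformMagnitude = 1.5,
                        muscleOffset = 30,
                        muscleRadius = 5,
                        qualityMode = "standard",
                        planeMode = "axial_like",
                        anisotropyRange = NULL) {
  if (is.null(anisotropyRange))
    anisotropyRange <- if (identical(planeMode, "coronal_like"))
      c(1.6, 2.1) else c(0.85, 1.2)
  ri <- regionIntensities
  if (is.na(ri[["lumen"]]))
    ri[["lumen"]] <- ri[["wall"]] * if (gelMode) 2.4 else 1.05
  if (identical(qualityMode, "degraded")) {
    noiseSigma <- 2 * noiseSigma
    ri[["fat"]] <- (ri[["fat"]] + ri[["wall"]]) / 2
  }
  new("PhantomSpec", gridShape = as.integer(gridShape),
      voxelSpacing = as.numeric(voxelSpacing),
      lumenRadiusRange = lumenRadiusRange,
      wallThicknessRange = wallThicknessRange,
      fatRingThicknessRange = fatRingThicknessRange,
      regionIntensities = ri, gelMode = gelMode, noiseSigma = noiseSigma,
      biasAmplitude = biasAmplitude, biasSmoothness = biasSmoothness,
      deformMagnitude = deformMagnitude, muscleOffset = muscleOffset,
      muscleRadius = muscleRadius, qualityMode = qualityMode,
      planeMode = planeMode, anisotropyRange = anisotropyRange)
}

# Per-boundary Fourier radius perturbation: r(theta) in mm, harmonics 2..4.
.fourierPerturb <- function(theta, mag) {
  if (mag <= 0) return(rep(0, length(theta)))
  amps <- runif(3, 0, mag / 3)
  phases <- runif(3, 0, 2 * pi)
  out <- 0
  for (k in 2:4) out <- out + amps[k - 1] * cos(k * theta + phases[k - 1])
  out
}

#' Generate one synthetic rectal-phantom case
#'
#' Deterministic in `(spec, seed)`. Per slice, the lumen/wall/fat boundaries
#' are concentric perturbed ellipses whose radii vary smoothly through
#' slices, so the nesting (lumen inside wall inside fat) holds by
#' construction; the muscle disk only claims background voxels and therefore
#' stays disjoint from the rectal labels. Intensities are assigned per label,
#' softened with a compact 3-tap in-plane blur (so eroded region cores keep
#' their configured mean exactly), then corrupted by the spec's bias field
#' and additive noise.
#'
#' @param spec a [PhantomSpec-class].
#' @param seed integer seed.
#' @return a [PhantomCase-class].
#' @export
generatePhantom <- function(spec, seed) {
  validObject(spec)
  seed <- as.integer(seed)
  withSeed(seed, {
    d <- spec@gridShape
    sp <- spec@voxelSpacing
    nz <- d[3]
    # in-plane physical coordinates relative to the grid center
    cx <- (d[1] - 1) * sp[1] / 2
    cy <- (d[2] - 1) * sp[2] / 2
    px <- (seq_len(d[1]) - 1) * sp[1] - cx
    py <- (seq_len(d[2]) - 1) * sp[2] - cy

    rL <- runif(1, spec@lumenRadiusRange[1], spec@lumenRadiusRange[2])
    tW <- runif(1, spec@wallThicknessRange[1], spec@wallThicknessRange[2])
    tF <- runif(1, spec@fatRingThicknessRange[1],
                spec@fatRingThicknessRange[2])
    # in-plane anisotropy (elongated rows for coronal-like plane statistics)
    aniso <- runif(1, spec@anisotropyRange[1], spec@anisotropyRange[2])
    jitter <- runif(2, -1, 1)              # mm, fixed center offset
    driftAmp <- runif(2, 0, 1)             # mm, smooth per-slice drift
    driftPh <- runif(2, 0, 2 * pi)
    # smooth through-slice scaling (dome-like taper toward end slices)
    zc <- (nz + 1) / 2
    zscale <- 1 - 0.45 * (((seq_len(nz) - zc) / max(1, nz - zc))^2)

    labels <- array(0L, d)
    magL <- spec@deformMagnitude
    # one Fourier perturbation per boundary, shared across slices
    thetaGrid <- seq(0, 2 * pi, length.out = 257)[-257]
    pertL <- .fourierPerturb(thetaGrid, magL)
    pertW <- .fourierPerturb(thetaGrid, magL * 0.6)
    pertF <- .fourierPerturb(thetaGrid, magL)
    lookup <- function(tab, th) {
      i <- as.integer(round(th %% (2 * pi) / (2 * pi) * 256)) %% 256 + 1
      tab[i]
    }

    for (k in seq_len(nz)) {
      ox <- jitter[1] + driftAmp[1] * sin(2 * pi * k / nz + driftPh[1])
      oy <- jitter[2] + driftAmp[2] * sin(2 * pi * k / nz + driftPh[2])
      X <- outer(px - ox, rep(1, d[2])) / aniso
      Y <- outer(rep(1, d[1]), py - oy)
      r <- sqrt(X^2 + Y^2)
      th <- atan2(Y, X)
      s <- zscale[k]
      bL <- pmax(0.5, rL * s + lookup(pertL, th))
      bW <- bL + pmax(0.6, tW * s + 0.5 * lookup(pertW, th))
      bF <- bW + pmax(0.8, tF * s + lookup(pertF, th))
      lab <- matrix(0L, d[1], d[2])
      lab[r <= bF] <- 3L
      lab[r <= bW] <- 2L
      lab[r <= bL] <- 1L
      # reference muscle: a disk at a fixed offset, background voxels only
      Xm <- outer(px - spec@muscleOffset, rep(1, d[2]))
      rm2 <- Xm^2 + outer(rep(1, d[1]), py)^2
      lab[rm2 <= spec@muscleRadius^2 & lab == 0L] <- 4L
      labels[, , k] <- lab
    }

    ri <- spec@regionIntensities
    lut <- c(ri[["background"]], ri[["lumen"]], ri[["wall"]], ri[["fat"]],
             ri[["muscle"]])
    image <- array(lut[labels + 1L], d)
    image <- blur3tap2d(image)
    if (spec@biasAmplitude > 0)
      image <- applyBiasField(image, spec@biasAmplitude, spec@biasSmoothness,
                              spacing = sp, seed = deriveSeed(seed, 1L))
    if (spec@noiseSigma > 0)
      image <- image + rnorm(length(image),
                             sd = spec@noiseSigma * ri[["wall"]])
    new("PhantomCase", image = image, labels = labels, spacing = sp,
        specId = paste0(spec@qualityMode, "_", spec@planeMode,
                        if (spec@gelMode) "_gel" else "_nogel"),
        seed = seed)
  })
}

#' Multiply a volume by a seeded smooth bias field
#'
#' The field is white noise smoothed to the requested correlation length and
#' rescaled so its deviation from 1 is exactly bounded by `amplitude`; the
#' returned volume is `image * field`. `amplitude = 0` returns the input
#' unchanged.
#'
#' @param image 3D numeric array.
#' @param amplitude peak deviation, in [0,1).
#' @param smoothness correlation length in mm.
#' @param spacing numeric(3) mm per axis.
#' @param seed integer seed making the field reproducible.
#' @return corrupted volume of the same shape.
#' @export
applyBiasField <- function(image, amplitude, smoothness, spacing, seed) {
  assertThat(amplitude >= 0 && amplitude < 1,
             "amplitude must lie in [0, 1)")
  if (amplitude == 0) return(image)
  withSeed(seed, {
    f <- array(rnorm(length(image)), dim(image))
    f <- gaussSmooth3d(f, smoothness / spacing)
    f <- f - mean(f)
    f <- f / max(abs(f), .Machine$double.eps)
    image * (1 + amplitude * f)
  })
}

#' Apply an institution-like affine intensity shift
#'
#' Emulates the marked scanner-to-scanner intensity variation between
#' institutions: `image -> scale * image + offset`, labels untouched.
#'
#' @param case a [PhantomCase-class].
#' @param scale multiplicative factor, > 0.
#' @param offset additive offset.
#' @return a shifted [PhantomCase-class].
#' @export
shiftInstitution <- function(case, scale, offset = 0) {
  assertThat(scale > 0, "scale must be > 0")
  new("PhantomCase", image = case@image * scale + offset,
      labels = case@labels, spacing = case@spacing,
      specId = paste0(case@specId, "_shifted"), seed = case@seed)
}

#' Generate a seeded phantom cohort with a manifest
#'
#' Per-case seeds are derived deterministically from the cohort seed, so the
#' whole cohort is a pure function of `(spec, nCases, seed)`.
#'
#' @param spec a [PhantomSpec-class].
#' @param nCases number of cases, >= 1.
#' @param seed cohort seed.
#' @param split split tag recorded in the manifest ("train", "val" or
#'   "test").
#' @param prefix case-id prefix.
#' @return list with `cases` (list of [PhantomCase-class]) and `manifest`
#'   (data.frame with case_id, image_path, label_path, split, spec_id, seed;
#'   paths are filled by [writeCohort()]).
#' @export
generateCohort <- function(spec, nCases, seed, split = "train",
                           prefix = "case") {
  assertThat(nCases >= 1, "nCases must be >= 1")
  ids <- sprintf("%s_%03d", prefix, seq_len(nCases))
  cases <- vector("list", nCases)
  seeds <- integer(nCases)
  for (i in seq_len(nCases)) {
    seeds[i] <- deriveSeed(seed, i)
    cases[[i]] <- tryCatch(generatePhantom(spec, seeds[i]),
                           error = function(e)
                             stop("case ", i, ": ", conditionMessage(e),
                                  call. = FALSE))
  }
  names(cases) <- ids
  manifest <- data.frame(case_id = ids, image_path = NA_character_,
                         label_path = NA_character_, split = split,
                         spec_id = cases[[1]]@specId, seed = seeds,
                         stringsAsFactors = FALSE)
  list(cases = cases, manifest = manifest)
}

#' Write a cohort to NIfTI volumes plus a CSV manifest
#'
#' Images are written as float NIfTI-1, labels as unsigned 8-bit integer,
#' with voxel spacing in the header. The manifest gains the file paths.
#'
#' @param cohort result of [generateCohort()].
#' @param dir output directory (created if missing).
#' @return the updated manifest data.frame (also written as `manifest.csv`).
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- cohort$manifest
  for (i in seq_len(nrow(man))) {
    case <- cohort$cases[[man$case_id[i]]]
    ip <- file.path(dir, paste0(man$case_id[i], "_image.nii"))
    lp <- file.path(dir, paste0(man$case_id[i], "_labels.nii"))
    writeVolume(case@image, case@spacing, ip, datatype = "float")
    writeVolume(case@labels, case@spacing, lp, datatype = "uint8")
    man$image_path[i] <- ip
    man$label_path[i] <- lp
  }
  write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  man
}

#' Read a cohort written by [writeCohort()]
#'
#' @param manifestPath path to `manifest.csv`.
#' @return list of `cases` and `manifest` as in [generateCohort()].
#' @export
readCohort <- function(manifestPath) {
  man <- read.csv(manifestPath, stringsAsFactors = FALSE)
  cases <- lapply(seq_len(nrow(man)), function(i) {
    img <- readVolume(man$image_path[i])
    lab <- readVolume(man$label_path[i])
    new("PhantomCase", image = img$data,
        labels = array(as.integer(round(lab$data)), dim(lab$data)),
        spacing = img$spacing, specId = as.character(man$spec_id[i]),
        seed = as.integer(man$seed[i]))
  })
  names(cases) <- man$case_id
  list(cases = cases, manifest = man)
}

#' Perturb a binary mask with smooth boundary noise
#'
#' Used to simulate a second expert reader: the mask is re-thresholded after
#' adding smooth spatial noise, which jitters the boundary by about
#' `strength` voxels while leaving the interior intact.
#'
#' @param mask 2D or 3D binary array.
#' @param strength boundary jitter scale in voxels.
#' @param seed integer seed.
#' @return perturbed binary array of the same shape.
#' @export
perturbMask <- function(mask, strength = 1, seed = 1) {
  d <- dim(mask)
  withSeed(seed, {
    noise <- array(rnorm(length(mask)), d)
    if (length(d) == 2) {
      dim(noise) <- c(d, 1L)
      sm <- gaussSmooth3d(noise, c(3, 3, 0))
      dim(sm) <- d
    } else sm <- gaussSmooth3d(noise, c(3, 3, 0))
    soft <- if (length(d) == 2) {
      tmp <- array(mask * 1, c(d, 1L))
      out <- gaussSmooth3d(tmp, c(1, 1, 0)); dim(out) <- d; out
    } else gaussSmooth3d(mask * 1, c(1, 1, 0))
    (soft + 0.25 * strength * sm) >= 0.5
  })
}
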