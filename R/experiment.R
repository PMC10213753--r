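#' Experiment configuration
#'
#' Bundles every stage configuration for a reproducible end-to-end phantom
#' experiment mirroring a multi-institutional evaluation: a training/
#' validation cohort and three holdout cohorts — C1-like (in-distribution,
#' with a simulated second reader), C2-like (shifted imaging
#' characteristics, by default visibly degraded image quality) and C3-like
#' (an "external institution" produced by an affine intensity shift). A
#' single global seed fans out deterministically to every stage.
#'
#' @param baseSpec [PhantomSpec-class] for the training distribution.
#' @param nTrain,nVal,nTest cohort sizes (nTest applies to each holdout
#'   cohort).
#' @param cohorts subset of c("C1", "C2", "C3") to evaluate.
#' @param c2Spec spec for the C2-like cohort; defaults to the
#'   quality-degraded variant of `baseSpec` (doubled noise, halved wall/fat
#'   contrast). Pass a no-gel or coronal-like spec to exercise those strata
#'   instead.
#' @param c3Shift list(scale, offset) applied to C3-like images.
#' @param preprocess a [preprocessConfig()].
#' @param unet a [unetConfig()] (head is set per model automatically).
#' @param train a [trainConfig()].
#' @param regions region-specific models to train.
#' @param trainMulticlass also train the multiclass model?
#' @param gridStep threshold-search grid spacing.
#' @param readerPerturb boundary-jitter strength of the simulated second
#'   reader (voxels).
#' @param seed global experiment seed.
#' @param outDir output directory, or `NULL` to skip writing files.
#' @return a list of class `ExperimentConfig`.
#' @export
experimentConfig <- function(baseSpec = phantomSpec(gridShape = c(64L, 64L, 5L),
                                                    lumenRadiusRange = c(3, 5.5),
                                                    wallThicknessRange = c(1.5, 2.5),
                                                    fatRingThicknessRange = c(3.5, 6),
                                                    muscleOffset = 20,
                                                    muscleRadius = 3),
                             nTrain = 60L, nVal = 10L, nTest = 20L,
                             cohorts = c("C1", "C2", "C3"),
                             c2Spec = NULL,
                             c3Shift = list(scale = 1.6, offset = 15),
                             preprocess = preprocessConfig(
                               cropFraction = 1.0,
                               netInputSize = baseSpec@gridShape[1]),
                             unet = unetConfig(
                               inputSize = preprocess$netInputSize,
                               depth = 2L, baseFilters = 6L),
                             train = trainConfig(epochs = 15L, batchSize = 8L),
                             regions = c("wall", "lumen"),
                             trainMulticlass = TRUE,
                             gridStep = 0.02,
                             readerPerturb = 1,
                             seed = 1L, outDir = NULL) {
  if (is.null(c2Spec)) {
    c2Spec <- phantomSpec(gridShape = baseSpec@gridShape,
                          voxelSpacing = baseSpec@voxelSpacing,
                          lumenRadiusRange = baseSpec@lumenRadiusRange,
                          wallThicknessRange = baseSpec@wallThicknessRange,
                          fatRingThicknessRange = baseSpec@fatRingThicknessRange,
                          gelMode = baseSpec@gelMode,
                          noiseSigma = baseSpec@noiseSigma,
                          biasAmplitude = baseSpec@biasAmplitude,
                          biasSmoothness = baseSpec@biasSmoothness,
                          deformMagnitude = baseSpec@deformMagnitude,
                          muscleOffset = baseSpec@muscleOffset,
                          muscleRadius = baseSpec@muscleRadius,
                          qualityMode = "degraded",
                          planeMode = baseSpec@planeMode)
  }
  structure(list(baseSpec = baseSpec, nTrain = as.integer(nTrain),
                 nVal = as.integer(nVal), nTest = as.integer(nTest),
                 cohorts = cohorts, c2Spec = c2Spec, c3Shift = c3Shift,
                 preprocess = preprocess, unet = unet, train = train,
                 regions = regions, trainMulticlass = trainMulticlass,
                 gridStep = gridStep, readerPerturb = readerPerturb,
                 seed = as.integer(seed), outDir = outDir),
            class = "ExperimentConfig")
}

# reference binary volume for a region on the preprocessed (pre-crop) grid
.referenceVolume <- function(prepCase, region) {
  lab <- prepCase$labels
  vol <- array(0, dim(lab))
  for (k in seq_len(dim(lab)[3]))
    vol[, , k] <- makeRegionTarget(lab[, , k], region)
  vol
}

# Predict one preprocessed case with a trained model and post-process to a
# binary volume per region on the pre-crop grid.
# For a sigmoid model `threshold` must be given and the result is a single
# volume; for a softmax model a named list of region volumes is returned.
.predictVolume <- function(model, prepCase, ppConfig, threshold = NULL) {
  nz <- dim(prepCase$image)[3]
  slices <- vector("list", nz)
  mappings <- vector("list", nz)
  for (k in seq_len(nz)) {
    s <- centerCropResize(prepCase$image[, , k], ppConfig, isMask = FALSE)
    mappings[[k]] <- attr(s, "cropMapping")
    attr(s, "cropMapping") <- NULL
    slices[[k]] <- s
  }
  probs <- predictSlices(model, slices)
  multiclass <- model@config$head == "softmax_multiclass"
  if (!multiclass) {
    assertThat(!is.null(threshold), "sigmoid model needs a threshold")
    vol <- array(0, dim(prepCase$image))
    for (k in seq_len(nz)) {
      m <- largestComponent(binarize(probs[[k]], threshold))
      vol[, , k] <- uncropPrediction(m, mappings[[k]], isMask = TRUE)
    }
    return(vol)
  }
  regions <- c("lumen", "wall", "fat")
  vols <- stats::setNames(lapply(regions, function(r)
    array(0, dim(prepCase$image))), regions)
  for (k in seq_len(nz)) {
    masks <- multiclassToMasks(probs[[k]],
                               classNames = c("lumen", "wall_annulus", "fat"))
    perRegion <- list(lumen = masks$lumen,
                      wall = (masks$lumen + masks$wall_annulus > 0) * 1,
                      fat = masks$fat)
    for (r in regions) {
      m <- largestComponent(perRegion[[r]])
      vols[[r]][, , k] <- uncropPrediction(m, mappings[[k]], isMask = TRUE)
    }
  }
  vols
}

#' Run a full region-specific vs. multiclass phantom experiment
#'
#' Generates the cohorts, preprocesses every case, trains the requested
#' region-specific U-Nets and the multiclass U-Net from identical
#' configurations (only the output head differs), optimizes the
#' binarization threshold of each sigmoid model on the validation split,
#' predicts and evaluates every holdout cohort (against the ground truth
#' playing the role of reader 1 and, on C1, a simulated second reader), and
#' assembles the median-DSC/HD/FD tables with rank-sum comparisons.
#'
#' @param config an [experimentConfig()].
#' @param verbose print stage progress?
#' @return list with `metrics` (per-case records), `summaries`,
#'   `comparisons` (region-specific vs multiclass per cohort), `thresholds`,
#'   `histories`, `models` and `provenance`; files are written to
#'   `config$outDir` when set (metrics.csv, report.csv, comparisons.csv,
#'   history_*.csv, provenance.json).
#' @export
runExperiment <- function(config = experimentConfig(), verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  seedOf <- function(i) deriveSeed(config$seed, i)
  pp <- config$preprocess

  say("generating cohorts")
  trainCoh <- generateCohort(config$baseSpec, config$nTrain, seedOf(1),
                             "train", "tr")
  valCoh <- generateCohort(config$baseSpec, config$nVal, seedOf(2),
                           "val", "va")
  testCoh <- list()
  if ("C1" %in% config$cohorts)
    testCoh$C1 <- generateCohort(config$baseSpec, config$nTest, seedOf(3),
                                 "test", "c1")
  if ("C2" %in% config$cohorts)
    testCoh$C2 <- generateCohort(config$c2Spec, config$nTest, seedOf(4),
                                 "test", "c2")
  if ("C3" %in% config$cohorts) {
    c3 <- generateCohort(config$baseSpec, config$nTest, seedOf(5),
                         "test", "c3")
    c3$cases <- lapply(c3$cases, shiftInstitution,
                       scale = config$c3Shift$scale,
                       offset = config$c3Shift$offset)
    testCoh$C3 <- c3
  }

  say("preprocessing")
  prep <- function(coh) lapply(coh$cases, preprocessCase, config = pp)
  trainPrep <- prep(trainCoh); valPrep <- prep(valCoh)
  testPrep <- lapply(testCoh, prep)

  models <- list(); histories <- list(); thresholds <- list()
  heads <- c(stats::setNames(config$regions, config$regions),
             if (config$trainMulticlass) c(multiclass = "multiclass"))
  mi <- 0
  for (nm in names(heads)) {
    mi <- mi + 1
    region <- heads[[nm]]
    say("training ", nm, " model")
    uCfg <- config$unet
    uCfg$head <- if (region == "multiclass") "softmax_multiclass"
                 else "sigmoid_binary"
    tCfg <- config$train
    tCfg$region <- region
    tCfg$seed <- seedOf(10 + mi)
    trainDs <- makeSliceDataset(trainPrep, region, pp)
    valDs <- makeSliceDataset(valPrep, region, pp)
    model <- buildUNet(uCfg, seed = seedOf(20 + mi))
    fit <- trainModel(model, trainDs, valDs, tCfg)
    models[[nm]] <- fit$model
    histories[[nm]] <- fit$history
    if (region != "multiclass") {
      say("optimizing threshold for ", nm)
      thresholds[[nm]] <- optimizeThreshold(fit$model, valDs,
                                            config$gridStep)
    }
  }

  say("evaluating holdout cohorts")
  metrics <- list()
  addRec <- function(rec, cohort, comparison) {
    rec$cohort <- cohort; rec$comparison <- comparison
    metrics[[length(metrics) + 1L]] <<- rec
  }
  for (cohName in names(testPrep)) {
    cases <- testPrep[[cohName]]
    for (ci in seq_along(cases)) {
      id <- names(cases)[ci]
      pc <- cases[[ci]]
      mcVols <- if (config$trainMulticlass)
        .predictVolume(models$multiclass, pc, pp) else NULL
      for (region in config$regions) {
        ref1 <- .referenceVolume(pc, region)
        pred <- .predictVolume(models[[region]], pc, pp,
                               thresholds[[region]]$threshold)
        addRec(evaluateCase(pred, ref1, pc$spacing, region, id),
               cohName, "region_vs_reader1")
        if (!is.null(mcVols) && region %in% names(mcVols))
          addRec(evaluateCase(mcVols[[region]], ref1, pc$spacing, region,
                              id), cohName, "multiclass_vs_reader1")
        if (cohName == "C1") {
          ref2 <- perturbMask(ref1, config$readerPerturb,
                              seed = deriveSeed(seedOf(6), ci)) * 1
          addRec(evaluateCase(pred, ref2, pc$spacing, region, id),
                 cohName, "region_vs_reader2")
          addRec(evaluateCase(ref1, ref2, pc$spacing, region, id),
                 cohName, "reader1_vs_reader2")
        }
      }
    }
  }
  metrics <- do.call(rbind, metrics)

  summaries <- summarizeCohort(metrics,
                               groupKeys = c("cohort", "comparison",
                                             "region"))
  comparisons <- list()
  if (config$trainMulticlass) {
    for (cohName in unique(metrics$cohort)) {
      a <- metrics[metrics$cohort == cohName &
                     metrics$comparison == "region_vs_reader1", ]
      b <- metrics[metrics$cohort == cohName &
                     metrics$comparison == "multiclass_vs_reader1", ]
      if (nrow(a) && nrow(b)) {
        cmp <- compareModels(a, b, alpha = 0.05, m = 6L,
                             labels = c("region_specific", "multiclass"))
        cmp$cohort <- cohName
        comparisons[[cohName]] <- cmp
      }
    }
  }
  comparisons <- if (length(comparisons))
    do.call(rbind, c(comparisons, make.row.names = FALSE)) else NULL

  provenance <- list(
    seed = config$seed,
    stageSeeds = list(train = seedOf(1), val = seedOf(2), c1 = seedOf(3),
                      c2 = seedOf(4), c3 = seedOf(5), reader2 = seedOf(6)),
    cohortSizes = list(train = config$nTrain, val = config$nVal,
                       test = config$nTest),
    unet = unclass(config$unet), train = unclass(config$train),
    preprocess = unclass(config$preprocess),
    regions = config$regions, gridStep = config$gridStep,
    thresholds = lapply(thresholds, function(t)
      list(threshold = t$threshold, criterion = t$criterionValue)),
    packageVersion = as.character(utils::packageVersion("rectseg")),
    rVersion = R.version.string)

  if (!is.null(config$outDir)) {
    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
    write.csv(metrics, file.path(config$outDir, "metrics.csv"),
              row.names = FALSE)
    write.csv(summaries, file.path(config$outDir, "report.csv"),
              row.names = FALSE)
    if (!is.null(comparisons))
      write.csv(comparisons, file.path(config$outDir, "comparisons.csv"),
                row.names = FALSE)
    for (nm in names(histories))
      write.csv(histories[[nm]],
                file.path(config$outDir, paste0("history_", nm, ".csv")),
                row.names = FALSE)
    jsonlite::write_json(provenance,
                         file.path(config$outDir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  list(metrics = metrics, summaries = summaries, comparisons = comparisons,
       thresholds = thresholds, histories = histories, models = models,
       provenance = provenance)
}

#' Scaled-down learning benchmark of the region-specific pipeline
#'
#' Runs the full pipeline at a reduced, single-CPU-friendly problem size:
#' seeded phantom cohorts (train/validation/in-distribution holdout plus a
#' quality-degraded holdout), preprocessing, training of the requested
#' region-specific U-Nets and the multiclass U-Net from identical
#' configurations, validation threshold optimization, and per-case
#' pseudo-volumetric Dice on both holdout cohorts. Distance metrics are
#' deliberately skipped here (use [runExperiment()] for the full report);
#' the question this answers is whether the pipeline learns and whether
#' region-specific context helps under degradation.
#'
#' @param seed integer seed fanned out to every stage.
#' @param config an [experimentConfig()]; sizes, architecture and recipe
#'   are taken from it.
#' @return list with `inDistribution` (data.frame: region, case_id, dice of
#'   the region-specific model), `degraded` (data.frame: region, case_id,
#'   dice_region, dice_multiclass), `medians` (per-region summary of both),
#'   `thresholds`, the trained `models` and the preprocessed in-distribution
#'   `holdout` cases.
#' @export
runLearningBenchmark <- function(seed = 1L, config = experimentConfig()) {
  seedOf <- function(i) deriveSeed(seed, i)
  pp <- config$preprocess
  prep <- function(coh) lapply(coh$cases, preprocessCase, config = pp)
  trainPrep <- prep(generateCohort(config$baseSpec, config$nTrain,
                                   seedOf(1), "train", "tr"))
  valPrep <- prep(generateCohort(config$baseSpec, config$nVal, seedOf(2),
                                 "val", "va"))
  c1Prep <- prep(generateCohort(config$baseSpec, config$nTest, seedOf(3),
                                "test", "c1"))
  c2Prep <- prep(generateCohort(config$c2Spec, config$nTest, seedOf(4),
                                "test", "c2"))

  models <- list(); thresholds <- list()
  heads <- c(config$regions, "multiclass")
  for (i in seq_along(heads)) {
    region <- heads[i]
    uCfg <- config$unet
    uCfg$head <- if (region == "multiclass") "softmax_multiclass"
                 else "sigmoid_binary"
    tCfg <- config$train
    tCfg$region <- region
    tCfg$seed <- seedOf(10 + i)
    fit <- trainModel(buildUNet(uCfg, seed = seedOf(20 + i)),
                      makeSliceDataset(trainPrep, region, pp),
                      valData = NULL, tCfg)
    models[[region]] <- fit$model
    if (region != "multiclass")
      thresholds[[region]] <- optimizeThreshold(
        fit$model, makeSliceDataset(valPrep, region, pp), config$gridStep)
  }

  diceOn <- function(prepCases, region, arm) {
    vapply(seq_along(prepCases), function(ci) {
      pc <- prepCases[[ci]]
      ref <- .referenceVolume(pc, region)
      pred <- if (arm == "region")
        .predictVolume(models[[region]], pc, pp,
                       thresholds[[region]]$threshold)
      else .predictVolume(models$multiclass, pc, pp)[[region]]
      diceCoef(pred, ref)
    }, numeric(1))
  }
  inDist <- do.call(rbind, lapply(config$regions, function(rg)
    data.frame(region = rg, case_id = names(c1Prep),
               dice = diceOn(c1Prep, rg, "region"))))
  degraded <- do.call(rbind, lapply(config$regions, function(rg)
    data.frame(region = rg, case_id = names(c2Prep),
               dice_region = diceOn(c2Prep, rg, "region"),
               dice_multiclass = diceOn(c2Prep, rg, "multiclass"))))
  medians <- do.call(rbind, lapply(config$regions, function(rg)
    data.frame(region = rg,
               in_distribution = median(inDist$dice[inDist$region == rg]),
               degraded_region =
                 median(degraded$dice_region[degraded$region == rg]),
               degraded_multiclass =
                 median(degraded$dice_multiclass[degraded$region == rg]))))
  rownames(inDist) <- rownames(degraded) <- rownames(medians) <- NULL
  list(inDistribution = inDist, degraded = degraded, medians = medians,
       thresholds = lapply(thresholds, `[[`, "threshold"),
       models = models, holdout = c1Prep)
}
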