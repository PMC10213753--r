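# rectseg

Region-specific deep-learning segmentation of rectal structures on
T2-weighted MRI — as a self-contained, CPU-only R package.

On post-chemoradiation rectal MRI, three regions need precise delineation
for staging and radiomics: the region enclosed by the outer rectal wall
boundary (B<sup>W</sup>), the lumen (B<sup>L</sup>), and the perirectal
fat (B<sup>F</sup>). Treatment effects blur these interfaces, manual
annotation is slow, and readers disagree. `rectseg` implements the
computational core of a region-specific segmentation study: one binary
U-Net per region versus a single multiclass U-Net, identical in every
respect except the output head, compared with overlap and boundary
metrics under multi-reader-style statistics.

The package provides, end to end:

* a **seeded synthetic phantom generator** for "rectal MRI" volumes with
  ground-truth labels (nested lumen/wall/fat ring anatomy, reference
  muscle disk, bias field, noise, bright-lumen vs. no-gel contrast,
  degraded-quality and coronal-like strata, institution-scale intensity
  shifts) — so the whole pipeline runs without patient data;
* the **harmonization chain**: resampling to a common resolution
  (0.781 × 0.781 × 4 mm by default), bias-field correction (self-contained
  smooth-divisor method, or N4 by delegation), intensity normalization by
  the mean of a reference muscle, and center-crop/resize to the network
  grid with an invertible mapping;
* **2D U-Nets** (contracting/expanding 3×3 conv + batch-norm blocks, 2×2
  max pooling, transposed-convolution upsampling, skip connections) with a
  sigmoid or softmax head, trained with soft Dice loss, Adam (lr 0.003),
  and on-the-fly flip/rotation augmentation — the layers and
  backpropagation are implemented natively on RcppArmadillo, so no deep
  learning framework is required;
* **post-processing**: validation-optimized binarization thresholds and
  largest-connected-component retention;
* **evaluation**: pseudo-volumetric Dice
  ( DSC(X,Y) = 2|X∩Y| / (|X|+|Y|) ), per-slice Hausdorff distance
  ( HD = max of the two directed max–min point distances ) and discrete
  Fréchet distance (dynamic-programming coupling recurrence, start-shift
  minimized for closed contours), in physical mm;
* **statistics**: median ± (labeled) dispersion tables, two-sided
  Wilcoxon rank-sum tests (exact enumeration for small tie-free samples),
  Bonferroni-corrected significance (0.05/6 ≈ 0.008 by default).

## Worked example

```r
library(rectseg)

# one synthetic annotated "scan"
spec <- phantomSpec(gridShape = c(64L, 64L, 5L),
                    lumenRadiusRange = c(3, 5.5),
                    wallThicknessRange = c(1.5, 2.5),
                    fatRingThicknessRange = c(3.5, 6),
                    muscleOffset = 20, muscleRadius = 3)
case <- generatePhantom(spec, seed = 42)
case
#> PhantomCase standard_axial_like_gel seed 42 : 64 x 64 x 5 voxels
#>   label voxels (bg/lumen/wall/fat/muscle): 17561/533/586/1570/230

# harmonize, then compare the truth with a simulated second reader
pc  <- preprocessCase(case, preprocessConfig(cropFraction = 1,
                                             netInputSize = 64L))
ref <- simplify2array(lapply(seq_len(5), function(k)
         makeRegionTarget(pc$labels[, , k], "wall")))
reader2 <- perturbMask(ref, strength = 1, seed = 9) * 1
evaluateCase(reader2, ref, pc$spacing, region = "wall", caseId = "tr_042")
#>   case_id region      dice hausdorff frechet n_slices_evaluated
#> 1  tr_042   wall 0.9982095     0.781   0.781                  5
```

A Dice of 0.998 with a median boundary distance of one voxel (0.781 mm
in-plane) is the level of agreement a careful second reader produces on
this easy, high-contrast phantom.

The full study analogue — train three region-specific U-Nets and one
multiclass U-Net, optimize thresholds on validation, evaluate all holdout
cohorts, and write metrics/report/provenance files — is one call:

```r
res <- runExperiment(experimentConfig(outDir = "experiment_out", seed = 1))
res$summaries      # median ± sd per cohort, comparison, region and metric
res$comparisons    # region-specific vs multiclass rank-sum tests
```

and the scaled learning benchmark (Dice-only, minutes on one CPU):

```r
runLearningBenchmark(seed = 1)$medians
```

A thin command-line front end with `phantom`, `experiment`, `benchmark`,
`evaluate` and `report` verbs lives at `inst/cli/rectseg.R`:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/rectseg.R", package = "rectseg"))')
Rscript "$CLI" phantom --out phantom_out --n 10 --seed 1
Rscript "$CLI" experiment --out experiment_out --seed 1
```

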