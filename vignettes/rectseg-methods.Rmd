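---
title: "Region-specific segmentation of rectal structures: models, metrics and phantom design"
author: "rectseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Region-specific segmentation of rectal structures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

On T2-weighted pelvic MRI of rectal cancer patients — especially after
neoadjuvant chemoradiation, when fibrosis and edema blur tissue interfaces —
three anatomical regions need precise delineation for radiological staging
and for downstream radiomics: the region enclosed by the **outer rectal
wall** boundary, the **lumen** (whose boundary is also the inner wall
boundary), and the **perirectal fat** out to the mesorectal fascia. Manual
annotation is slow and shows real inter-reader disagreement.

`rectseg` implements the full computational side of a region-specific
segmentation study: instead of one multiclass network that labels every
pixel at once, one binary U-Net is trained *per region*, each with
identical architecture and training recipe, differing from the multiclass
model only in the output head (sigmoid vs. softmax). The package contains
everything needed to run and evaluate that comparison — a synthetic
phantom cohort generator, the MRI harmonization chain, the networks and
training loop, post-processing, contour agreement metrics, and the
statistical reporting layer — with no patient data and no GPU.

## The phantom generator

Real cohorts of annotated post-treatment rectal MRI are private. The
generator (`phantomSpec()`, `generatePhantom()`, `generateCohort()`)
produces the *structure* such cohorts exhibit, so that every pipeline stage
is exercised honestly:

* **Nested anatomy.** Per slice, the lumen disk, wall annulus and fat ring
  are concentric perturbed ellipses. Boundary radii are built
  *cumulatively* (lumen radius, plus a positive wall thickness, plus a
  positive fat thickness), so the nesting `lumen ⊂ wall ⊂ fat` holds by
  construction on every slice — an invariant the tests verify. Radii taper
  smoothly toward the end slices and the center drifts slowly through the
  stack.
* **Boundary irregularity.** Low-order Fourier perturbations (harmonics
  2–4, magnitude `deformMagnitude` in mm) make contours non-circular but
  simple.
* **Reference muscle.** A separate disk at a fixed offset plays the role
  of the obturator internus muscle, the intensity-normalization reference.
  It only ever claims background voxels, so it stays disjoint from the
  rectal labels.
* **Contrast regimes.** `gelMode = TRUE` gives a bright lumen
  (endorectal gel, lumen ≈ 2.4× wall intensity); `gelMode = FALSE` puts
  the lumen within 10% of the wall intensity, reproducing how lumen
  boundaries are obscured without gel. `qualityMode = "degraded"` doubles
  the noise and halves the wall/fat contrast — the "visibly poor quality"
  stratum. `planeMode = "coronal_like"` elongates the anatomy in-plane,
  a 2D-level stand-in for a different acquisition plane (the networks are
  2D, so slice-level shape statistics are what matters).
* **Corruptions.** A smooth multiplicative bias field (white noise
  smoothed to `biasSmoothness` mm, rescaled so its deviation from 1 is
  exactly bounded by `biasAmplitude`) and additive Gaussian noise
  (`noiseSigma`, as a fraction of wall intensity). Intensities are
  softened by a compact 3-tap partial-volume blur whose support is one
  pixel, so eroded region cores keep their configured means exactly —
  which is what makes the generator testable against its own parameters.

What the phantom does **not** emulate: tissue texture, treatment-effect
heterogeneity (fibrosis, edema), Rician noise statistics (Gaussian is an
adequate stand-in at these SNRs and could be swapped behind the same
interface), k-space artifacts, or true 3D reformatting. Consequences for
interpretation: passing tests show the *pipeline* learns and the
*comparison machinery* works; absolute Dice values on phantoms are higher
than on real MRI, and the no-gel regime is close to information-free here
(the only lumen cue in a texture-free image is a 5% intensity difference),
so the quality-degraded stratum is the default C2-like cohort.

## Preprocessing

The harmonization chain runs in a fixed order, mirroring how
multi-institutional MRI has to be made commensurable:

1. **Resampling** to a common spacing (default 0.781 × 0.781 × 4 mm),
   trilinear for images, nearest-neighbor for label volumes, under the
   package-wide convention `position = index × spacing` (0-based, identity
   orientation).
2. **Bias-field correction.** The default `smooth_div` divides the volume
   by a heavily Gaussian-smoothed copy of itself (sigma = half the
   in-plane extent — wide enough that anatomy barely leaks into the
   divisor while the smooth trend is captured) and rescales to preserve
   the global mean; it is self-contained and fast. `n4` delegates to an installed SimpleITK N4
   implementation through the system `python` for higher fidelity.
3. **Muscle normalization.** Division by the mean intensity over the full
   3D muscle mask, making that mean exactly 1. Division (rather than a
   z-score against the muscle) is the simplest reading of normalizing
   "with respect to the mean intensity" of a reference structure; it is
   scale-invariant and idempotent.
4. **Center-crop and resize** of each slice to the network input size
   (default crop fraction 0.5, 128 × 128), bilinear for images and
   nearest-neighbor for masks. The crop geometry is recorded so
   predictions are mapped *back* to the pre-crop grid before evaluation —
   distances in mm must not depend on the network input size.

## Networks and training

The U-Net (`unetConfig()`, `buildUNet()`) uses `depth` contracting levels
of two 3×3 convolutions with batch normalization and ReLU followed by 2×2
max pooling, a bottleneck block, and a mirrored expanding path of 2×2
transposed convolutions with skip concatenation. "Same" padding keeps the
output at the input size. Dropout (rate 0.2) sits after the second
convolution of each block; the original architecture leaves the placement
open, and this is the most common choice. The layers themselves (im2col +
GEMM convolutions, pooling, up-convolutions, batch-norm) are implemented
in the package on RcppArmadillo with hand-written backpropagation; every
kernel is finite-difference checked in the test suite.

Training (`trainModel()`) follows one recipe for all models: Adam at
learning rate 0.003 (constant — no schedule), batch size 16, 50 epochs,
soft Dice loss

$$\mathcal{L} = 1 - \frac{2\sum_i p_i t_i + \varepsilon}
                         {\sum_i p_i + \sum_i t_i + \varepsilon},
  \qquad \varepsilon = 10^{-6},$$

averaged over non-background classes for the softmax head, with
on-the-fly augmentation: vertical flips (probability 0.5; "vertical" is
taken as row reversal, configurable) and rotations uniform in ±30°.
Slices with empty targets stay in training — a region can be genuinely
absent on end slices, and ε keeps the loss well defined. The final-epoch
weights are returned; no early stopping or model selection is applied.

The **wall** task targets the *filled* region enclosed by the outer wall
boundary (lumen + wall labels): the three tasks are named after the
boundaries they recover, and the filled reading makes the wall target a
simply connected region whose boundary is exactly the outer wall. The
wall annulus alone remains available as a `wall_annulus` target for
sensitivity analyses.

## Post-processing

Sigmoid outputs are binarized at a threshold optimized per model on the
validation split: the deployed pipeline (binarize, then keep the largest
connected component) is scored by mean per-case pseudo-volumetric Dice on
a grid of step 0.01 over (0, 1), ties broken to the smallest threshold.
Connected components use 8-connectivity per 2D slice (the models and
thresholds are 2D); a 26-connectivity 3D mode exists behind the
`connectivity` argument. Softmax outputs take a per-pixel argmax (ties to
the lowest channel index) instead of a threshold.

## Evaluation metrics

* **Dice:** $DSC(X,Y) = 2|X\cap Y|/(|X|+|Y|)$, computed over the stacked
  3D masks (pseudo-volumetric). Two empty masks score 1 (perfect
  agreement on absence); exactly one empty mask scores 0.
* **Hausdorff distance:** the symmetric max–min Euclidean distance
  between boundary points, per slice, in mm.
* **Fréchet distance:** the order-respecting "dog-leash" distance,
  implemented as the discrete Fréchet distance on the polygonal contours
  via the standard dynamic-programming coupling recurrence. The
  discretization error is bounded by one contour segment, which is at
  most one voxel diagonal by construction of the boundary extractor.
  Closed contours have no canonical start point, so the distance is
  minimized over cyclic shifts of one contour (every `max(1, n/64)`-th
  shift; exact minimization behind `exactShifts = TRUE`) and over both
  orientations. The discrete Fréchet distance always dominates the
  Hausdorff distance of the same point sets, which the tests assert on
  every evaluated pair.

Boundaries come from marching-squares contours of the 0.5 level set
(`grDevices::contourLines` on a zero-padded mask), scaled to physical mm;
only the largest contour per slice enters the distance metrics, matching
the post-CCA single-component masks. Per case, HD and FD are medians over
slices where both masks are nonempty; slices where exactly one side is
empty are excluded from the distance medians but fully counted in the 3D
Dice. Distances are reported in mm (the natural physical unit after
resampling to a common resolution).

## Statistical reporting

Cohort tables report the median of each metric together with an
explicitly labeled standard deviation — published tables of this kind
print "median ± value" without defining the dispersion, so the package
refuses to fold the two into one ambiguous column. Two-arm comparisons
use a two-sided Wilcoxon rank-sum test: exact enumeration when the pooled
sample has at most 12 tie-free observations, otherwise the normal
approximation with tie and continuity correction. Significance is judged
at the Bonferroni threshold α/m with m = 6 comparisons by default —
consistent with a printed cutoff of 0.008 ≈ 0.05/6 — and m configurable,
since the exact grouping of comparisons behind such cutoffs is ambiguous.

## Experiment analogues and the simulated second reader

`runExperiment()` mirrors a three-cohort holdout design: C1-like
(in-distribution; model-vs-truth plays model-vs-reader-1, and a simulated
second reader — the truth masks re-thresholded after adding smooth spatial
noise, jittering boundaries by about one voxel — exercises the
inter-reader machinery), C2-like (shifted imaging characteristics;
quality-degraded by default), and C3-like (an affine intensity shift
standing in for an external institution, which the muscle normalization
should absorb). All models share one configuration; only the output head
differs, so parameter counts differ only in the 1×1 output layer.

## Scaled problem sizes

The package's own benchmark (`runLearningBenchmark()`, also used by the
acceptance script) runs the pipeline at a single-CPU scale chosen once:
64 × 64 × 5 phantoms at 0.781 × 0.781 × 4 mm, 60 training / 10 validation
/ 20 holdout cases per cohort, depth-2 U-Nets with 6 base filters, 15
epochs at batch size 8, threshold grid step 0.02, and Dice-only holdout
scoring (the full contour metrics live in `runExperiment()`). These sizes
are the package's declared benchmark conditions, not tuned quantities; at
this scale the region-specific wall and lumen models reach median holdout
Dice well above 0.8 and the full three-seed benchmark runs in minutes.

## Numerical choices, in one place

* Soft-Dice smoothing ε = 1e-6; both-empty Dice = 1; one-empty Dice = 0.
* Threshold grid 0.01 (benchmark uses 0.02), ties to the smallest value.
* CCA: 8-connectivity, per slice; component ties to the first label in
  column-major scan order; max-pooling argmax ties to scan order as well.
* Softmax argmax ties to the lowest class index.
* He-normal weight initialization from a seeded RNG; batch-norm momentum
  0.1, eps 1e-5; Adam β = (0.9, 0.999), eps 1e-8.
* All stage seeds derive deterministically from one experiment seed, and
  every seeded helper restores the caller's RNG stream.

## Known limitations

* Phantom realism bounds what the benchmark can show (see above); in
  particular the no-gel stratum is nearly information-free without
  texture, and directional model comparisons on it are not meaningful.
  More generally, both model families sit near the phantom's performance
  ceiling even on the degraded stratum, so region-specific vs. multiclass
  *differences* there are small and seed-dependent: the benchmark treats
  that comparison as a soft, warning-level expectation, because the effect
  size on easy synthetic anatomy need not match real MRI, where boundary
  evidence is far weaker.
* The training loop is single-threaded CPU code; it is meant for
  method-scale experiments, not for 128 × 128 × 50-epoch clinical-scale
  training, although the code paths are identical.
* Bit-identical reruns are guaranteed under a fixed BLAS/thread
  configuration; changing the BLAS can change floating-point summation
  orders.
* Orientation matrices are not handled; volumes are assumed axis-aligned
  with positive spacings.
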