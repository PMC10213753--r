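# Shared fixtures: a small phantom geometry that fits a 64 x 64 grid, and
# cached generated cases so independent tests do not regenerate them.

smallSpec <- function(...) {
  args <- list(...)
  defaults <- list(gridShape = c(64L, 64L, 6L),
                   lumenRadiusRange = c(3, 5.5),
                   wallThicknessRange = c(1.5, 2.5),
                   fatRingThicknessRange = c(3.5, 6),
                   muscleOffset = 20, muscleRadius = 3)
  do.call(phantomSpec, utils::modifyList(defaults, args))
}

# noiseless, bias-free, undeformed variant for exact-intensity checks
cleanSpec <- function(...) {
  smallSpec(noiseSigma = 0, biasAmplitude = 0, deformMagnitude = 0, ...)
}

.fixtureCache <- new.env(parent = emptyenv())

cachedCase <- function(key, spec, seed) {
  if (is.null(.fixtureCache[[key]]))
    .fixtureCache[[key]] <- generatePhantom(spec, seed)
  .fixtureCache[[key]]
}

# random blob mask via thresholded smoothed noise (always at least 1 pixel)
randomBlobMask <- function(n = 40, seed = 1) {
  withr::with_seed(seed, {
    z <- matrix(rnorm(n * n), n, n)
    sm <- rectseg:::gaussSmooth3d(array(z, c(n, n, 1)), c(4, 4, 0))[, , 1]
    m <- (sm > stats::quantile(sm, 0.75)) * 1
    if (!any(m > 0)) m[n %/% 2, n %/% 2] <- 1
    m
  })
}
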