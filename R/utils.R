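#' @useDynLib rectseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats rnorm runif median sd quantile wilcox.test pnorm
#' @importFrom utils read.csv write.csv head tail combn
#' @importFrom grDevices contourLines
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards so seeded helpers do not perturb each other.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Deterministic derivation of a child seed from a parent seed and an index;
# kept strictly below 2^31 so it is always a valid R integer seed.
deriveSeed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(index) * 104729 + 13) %%
               2147483629)
}

# Row-stochastic 1D Gaussian smoothing matrix with replicate (renormalized)
# boundary handling; `sigma` in sample units.
gaussSmoothMatrix <- function(n, sigma) {
  if (sigma <= 0 || n == 1) return(diag(n))
  idx <- seq_len(n)
  K <- exp(-outer(idx, idx, "-")^2 / (2 * sigma^2))
  K / rowSums(K)
}

# Apply a matrix operator along one axis of a 3D array (tensor contraction
# via GEMM); used by smoothing and grid resampling.
applyAlongAxis <- function(vol, M, axis) {
  d <- dim(vol)
  perm <- c(axis, setdiff(1:3, axis))
  v <- aperm(vol, perm)
  dv <- dim(v)
  v <- M %*% matrix(v, nrow = dv[1])
  dim(v) <- c(nrow(M), dv[2], dv[3])
  aperm(v, order(perm))
}

# Separable 3D Gaussian smoothing; sigma given per axis in voxel units.
gaussSmooth3d <- function(vol, sigma) {
  for (ax in 1:3) {
    if (sigma[ax] > 0 && dim(vol)[ax] > 1)
      vol <- applyAlongAxis(vol, gaussSmoothMatrix(dim(vol)[ax], sigma[ax]), ax)
  }
  vol
}

# Compact 3-tap boundary blur ([1 2 1]/4 per in-plane axis) used to imitate
# partial-volume softening without touching eroded region interiors.
blur3tap2d <- function(vol) {
  k <- c(0.25, 0.5, 0.25)
  d <- dim(vol)
  tap <- function(n) {
    M <- diag(n) * k[2]
    M[cbind(2:n, 1:(n - 1))] <- k[1]
    M[cbind(1:(n - 1), 2:n)] <- k[3]
    M[1, 1] <- M[1, 1] + k[1]
    M[n, n] <- M[n, n] + k[3]
    M
  }
  vol <- applyAlongAxis(vol, tap(d[1]), 1)
  applyAlongAxis(vol, tap(d[2]), 2)
}

# Binary erosion with a square (2D, per slice) structuring element of
# half-width `r`, via EBImage.
erodeMask <- function(mask, r = 2) {
  if (r <= 0) return(mask)
  brush <- EBImage::makeBrush(2 * r + 1, shape = "box")
  d <- dim(mask)
  if (length(d) == 2) {
    out <- EBImage::erode(mask * 1, brush) > 0.5
  } else {
    out <- array(FALSE, d)
    for (k in seq_len(d[3]))
      out[, , k] <- EBImage::erode(mask[, , k] * 1, brush) > 0.5
  }
  out
}

assertThat <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}
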