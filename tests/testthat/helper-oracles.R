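# Independent brute-force oracles the implementation is checked against.

# O(n^2) all-pairs Hausdorff distance on two point matrices
hausdorffOracle <- function(A, B) {
  D <- sqrt(outer(rowSums(A^2), rep(1, nrow(B))) +
              outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * A %*% t(B))
  D[D < 0 | is.na(D)] <- 0
  max(max(apply(D, 1, min)), max(apply(D, 2, min)))
}

# memoized recursive-definition discrete Frechet distance (open polylines)
frechetOracle <- function(P, Q) {
  np <- nrow(P); nq <- nrow(Q)
  memo <- matrix(NA_real_, np, nq)
  d <- function(i, j) sqrt(sum((P[i, ] - Q[j, ])^2))
  rec <- function(i, j) {
    if (!is.na(memo[i, j])) return(memo[i, j])
    v <- if (i == 1 && j == 1) d(1, 1)
    else if (i == 1) max(rec(1, j - 1), d(1, j))
    else if (j == 1) max(rec(i - 1, 1), d(i, 1))
    else max(min(rec(i - 1, j), rec(i - 1, j - 1), rec(i, j - 1)), d(i, j))
    memo[i, j] <<- v
    v
  }
  rec(np, nq)
}

# exhaustive-enumeration two-sided rank-sum p-value (no ties assumed)
ranksumOracle <- function(a, b) {
  nn <- length(a) + length(b)
  w <- sum(rank(c(a, b))[seq_along(a)])
  ws <- colSums(utils::combn(nn, length(a)))
  min(1, 2 * min(mean(ws <= w), mean(ws >= w)))
}

# random simple closed contour (perturbed ellipse) as an n x 2 point matrix
randomContour <- function(npts, seed, scale = 10) {
  withr::with_seed(seed, {
    th <- sort(runif(npts, 0, 2 * pi))
    r <- scale * (1 + 0.3 * sin(2 * th + runif(1, 0, pi)) +
                    0.1 * cos(3 * th))
    cbind(r * cos(th) + rnorm(1, sd = 2), r * sin(th) + rnorm(1, sd = 2))
  })
}
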