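#' Dice similarity coefficient of two binary masks
#'
#' `DSC(X, Y) = 2|X intersect Y| / (|X| + |Y|)`. Two empty masks agree
#' perfectly on absence and score 1 by convention; exactly one empty mask
#' scores 0.
#'
#' @param X,Y binary arrays of equal shape (any dimensionality).
#' @return scalar in \[0, 1\].
#' @export
diceCoef <- function(X, Y) {
  assertThat(identical(dim(X), dim(Y)), "masks must share shape")
  sx <- sum(X > 0); sy <- sum(Y > 0)
  if (sx + sy == 0) return(1)
  2 * sum(X > 0 & Y > 0) / (sx + sy)
}

#' Extract sub-pixel boundary contours from a binary mask
#'
#' Marching-squares contours of the 0.5 level set (the mask is zero-padded
#' first so boundary-touching regions still close), scaled to physical mm
#' under the `position = index * spacing` convention, ordered by enclosed
#' area descending. Each contour is a closed, ordered point sequence.
#'
#' @param mask 2D binary array.
#' @param spacing numeric(2) in-plane spacing, mm.
#' @return list of contours, each a list with `points` (n x 2 matrix, mm),
#'   `closed` (logical) and `area` (enclosed area, mm^2); empty list for an
#'   empty mask.
#' @export
extractBoundary <- function(mask, spacing = c(1, 1)) {
  if (!any(mask > 0)) return(list())
  d <- dim(mask)
  z <- matrix(0, d[1] + 2, d[2] + 2)
  z[2:(d[1] + 1), 2:(d[2] + 1)] <- (mask > 0) * 1
  xs <- ((0:(d[1] + 1)) - 1) * spacing[1]
  ys <- ((0:(d[2] + 1)) - 1) * spacing[2]
  cl <- contourLines(xs, ys, z, levels = 0.5)
  out <- lapply(cl, function(co) {
    pts <- cbind(co$x, co$y)
    closed <- sqrt(sum((pts[1, ] - pts[nrow(pts), ])^2)) < 1e-9
    if (closed && nrow(pts) > 1) pts <- pts[-nrow(pts), , drop = FALSE]
    # shoelace area (absolute)
    n <- nrow(pts)
    nxt <- c(2:n, 1)
    area <- abs(sum(pts[, 1] * pts[nxt, 2] - pts[nxt, 1] * pts[, 2])) / 2
    list(points = pts, closed = closed, area = area)
  })
  out[order(vapply(out, `[[`, numeric(1), "area"), decreasing = TRUE)]
}

.contourPoints <- function(x) {
  if (is.list(x) && !is.null(x$points)) x$points else as.matrix(x)
}

#' Hausdorff distance between two contours
#'
#' The maximum over both directions of the point-to-set Euclidean distance
#' between the two boundaries:
#' `max(sup_a inf_b d(a,b), sup_b inf_a d(a,b))` over the contour points.
#'
#' @param A,B contours from [extractBoundary()] or plain n x 2 point
#'   matrices (same units).
#' @return scalar distance, 0 iff the point sets coincide.
#' @export
hausdorffDist <- function(A, B) {
  pa <- .contourPoints(A); pb <- .contourPoints(B)
  assertThat(nrow(pa) >= 1 && nrow(pb) >= 1, "empty contour")
  .hausdorffCpp(pa, pb)
}

#' Discrete Fréchet distance between two contours
#'
#' The order-respecting "dog-leash" curve distance, computed with the
#' standard dynamic-programming coupling recurrence on the polygonal point
#' sequences. For a pair of closed contours the start point of the second
#' contour is arbitrary, so the distance is minimized over cyclic shifts of
#' its starting index (every `max(1, n/64)`-th shift by default, every shift
#' when `exactShifts = TRUE`) and over both traversal orientations. Always
#' at least as large as [hausdorffDist()] on the same pair.
#'
#' @param A,B contours from [extractBoundary()] or plain n x 2 point
#'   matrices.
#' @param exactShifts minimize over every cyclic shift instead of the coarse
#'   grid.
#' @return scalar distance.
#' @export
frechetDist <- function(A, B, exactShifts = FALSE) {
  pa <- .contourPoints(A); pb <- .contourPoints(B)
  assertThat(nrow(pa) >= 1 && nrow(pb) >= 1, "empty contour")
  closed <- (is.list(A) && isTRUE(A$closed)) &&
    (is.list(B) && isTRUE(B$closed))
  if (!closed) return(.frechetCpp(pa, pb))
  n <- nrow(pb)
  shifts <- seq(0, n - 1, by = if (exactShifts) 1L else max(1L, n %/% 64L))
  best <- Inf
  for (rev in c(FALSE, TRUE)) {
    pbo <- if (rev) pb[n:1, , drop = FALSE] else pb
    for (s in shifts) {
      idx <- ((seq_len(n) - 1 + s) %% n) + 1
      d <- .frechetCpp(pa, pbo[idx, , drop = FALSE])
      if (d < best) best <- d
    }
  }
  best
}

#' Evaluate one case on a pseudo-volumetric basis
#'
#' Dice is computed over the full stacked 3D masks. Hausdorff and Fréchet
#' distances are computed per slice between the largest boundary contour of
#' the prediction and of the reference (in physical mm), on slices where
#' both are nonempty, and summarized by the median across those slices;
#' slices where exactly one side is empty are excluded from the distance
#' medians but fully counted in the 3D Dice.
#'
#' @param pred 3D binary mask volume (prediction).
#' @param ref 3D binary mask volume (reference annotation), nonempty on at
#'   least one slice.
#' @param spacing numeric(3) mm; the first two entries set the in-plane
#'   scale of the contours.
#' @param region region tag recorded in the output.
#' @param caseId case identifier recorded in the output.
#' @return one-row data.frame (a `MetricRecord`): case_id, region, dice,
#'   hausdorff, frechet, n_slices_evaluated.
#' @export
evaluateCase <- function(pred, ref, spacing = c(1, 1, 1), region = "wall",
                         caseId = "case") {
  assertThat(identical(dim(pred), dim(ref)), "grid mismatch")
  dice <- diceCoef(pred, ref)
  nz <- dim(pred)[3]
  hds <- c(); fds <- c()
  for (k in seq_len(nz)) {
    pk <- pred[, , k]; rk <- ref[, , k]
    if (!any(pk > 0) || !any(rk > 0)) next
    cp <- extractBoundary(pk, spacing[1:2])[[1]]
    cr <- extractBoundary(rk, spacing[1:2])[[1]]
    hds <- c(hds, hausdorffDist(cp, cr))
    fds <- c(fds, frechetDist(cp, cr))
  }
  data.frame(case_id = caseId, region = region, dice = dice,
             hausdorff = if (length(hds)) median(hds) else NA_real_,
             frechet = if (length(fds)) median(fds) else NA_real_,
             n_slices_evaluated = length(hds), stringsAsFactors = FALSE)
}

#' Evaluate a set of predicted volumes against references
#'
#' @param preds named list of 3D binary prediction volumes.
#' @param refs named list of matching reference volumes.
#' @param spacing numeric(3) mm.
#' @param region region tag.
#' @return data.frame of per-case `MetricRecord` rows.
#' @export
evaluateCohort <- function(preds, refs, spacing = c(1, 1, 1),
                           region = "wall") {
  ids <- names(preds) %||% as.character(seq_along(preds))
  do.call(rbind, lapply(seq_along(preds), function(i)
    evaluateCase(preds[[i]], refs[[i]], spacing, region, ids[i])))
}
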