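#' Two-sided Wilcoxon rank-sum test
#'
#' Exact enumeration of the rank-sum null distribution when the pooled
#' sample has at most 12 observations and no ties (two-sided p as twice the
#' smaller tail, capped at 1); otherwise the normal approximation with tie
#' and continuity correction (via [stats::wilcox.test()]). Symmetric in its
#' arguments.
#'
#' @param a,b numeric samples, each nonempty.
#' @return two-sided p-value.
#' @export
ranksumTest <- function(a, b) {
  assertThat(length(a) >= 1 && length(b) >= 1, "empty sample")
  pooled <- c(a, b)
  na <- length(a); nn <- length(pooled)
  if (nn <= 12 && !anyDuplicated(pooled)) {
    w <- sum(rank(pooled)[seq_len(na)])
    # under H0 every na-subset of the ranks 1..nn is equally likely
    ws <- colSums(combn(nn, na))
    pLow <- mean(ws <= w)
    pHigh <- mean(ws >= w)
    return(min(1, 2 * min(pLow, pHigh)))
  }
  stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise error rate, in (0, 1).
#' @param m number of comparisons, >= 1.
#' @return `alpha / m`.
#' @export
bonferroniThreshold <- function(alpha = 0.05, m = 6L) {
  assertThat(alpha > 0 && alpha < 1, "alpha must lie in (0, 1)")
  assertThat(m >= 1, "m must be >= 1")
  alpha / m
}

#' Summarize metric records per group
#'
#' For each group (default: comparison x region) reports the median and, as
#' an explicitly labeled dispersion, the standard deviation of each metric,
#' together with the record count. The tables this mirrors print
#' "median +/- value" without defining the dispersion, so both statistics
#' are kept side by side rather than folded into one column.
#'
#' @param records data.frame of `MetricRecord` rows ([evaluateCase()]),
#'   optionally with extra grouping columns such as `comparison`.
#' @param groupKeys character vector of grouping column names present in
#'   `records`.
#' @param metrics metric columns to summarize.
#' @return long data.frame: group keys, metric, median, sd, n.
#' @export
summarizeCohort <- function(records,
                            groupKeys = intersect(c("comparison", "region"),
                                                  names(records)),
                            metrics = c("dice", "hausdorff", "frechet")) {
  assertThat(nrow(records) >= 1, "no records")
  assertThat(all(groupKeys %in% names(records)), "missing grouping columns")
  key <- interaction(records[groupKeys], drop = TRUE, sep = "\r")
  rows <- lapply(levels(key), function(lv) {
    sub <- records[key == lv, , drop = FALSE]
    do.call(rbind, lapply(metrics, function(mt) {
      v <- sub[[mt]][is.finite(sub[[mt]])]
      cbind(sub[1, groupKeys, drop = FALSE],
            data.frame(metric = mt,
                       median = if (length(v)) median(v) else NA_real_,
                       sd = if (length(v) > 1) sd(v) else 0,
                       n = length(v), stringsAsFactors = FALSE))
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare two arms of metric records with rank-sum tests
#'
#' For every region and metric shared by the two record sets, reports the
#' medians of both arms, the two-sided rank-sum p-value, and a significance
#' flag at the Bonferroni threshold `alpha / m`.
#'
#' @param recordsA,recordsB data.frames of `MetricRecord` rows covering the
#'   same regions (e.g. region-specific vs. multiclass models).
#' @param alpha family-wise error rate.
#' @param m number of comparisons the correction accounts for.
#' @param labels character(2) naming the two arms.
#' @return data.frame of class `ComparisonReport`: region, metric, medians,
#'   n per arm, p_value, threshold, significant.
#' @export
compareModels <- function(recordsA, recordsB, alpha = 0.05, m = 6L,
                          labels = c("A", "B")) {
  regions <- sort(unique(recordsA$region))
  assertThat(setequal(regions, unique(recordsB$region)),
             "record sets cover different regions")
  thr <- bonferroniThreshold(alpha, m)
  metrics <- c("dice", "hausdorff", "frechet")
  rows <- list()
  for (rg in regions) {
    for (mt in metrics) {
      va <- recordsA[[mt]][recordsA$region == rg]
      vb <- recordsB[[mt]][recordsB$region == rg]
      va <- va[is.finite(va)]; vb <- vb[is.finite(vb)]
      p <- if (length(va) && length(vb)) ranksumTest(va, vb) else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        region = rg, metric = mt,
        median_a = if (length(va)) median(va) else NA_real_,
        median_b = if (length(vb)) median(vb) else NA_real_,
        n_a = length(va), n_b = length(vb),
        p_value = p, threshold = thr,
        significant = isTRUE(p < thr), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "labels") <- labels
  class(out) <- c("ComparisonReport", class(out))
  out
}
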