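# Thresholded-overlap statistics: fraction-of-max thresholding, pairwise
# overlap counts, and the p and r ratios used to compare montage pairs.

#' Threshold a field at a fraction of its maximum
#'
#' Returns the set of nodes whose value is strictly greater than
#' `fraction * max(field)` (default 50% of maximum). When `labels` is given,
#' both the maximum and the candidate nodes are restricted to labelled nodes,
#' so thresholding and the lobe statistics see the same support. Ties at
#' exactly the threshold are excluded; the maximum node itself always passes.
#'
#' @param field a [FieldVector-class] with a positive maximum.
#' @param fraction threshold fraction in (0, 1).
#' @param labels optional [AtlasLabelTable-class] restricting the support.
#' @return A [ThresholdedSet-class].
#' @examples
#' f <- FieldVector(1:4, c(0.03, 0.02, 0.014, 0.001), montageName = "toy")
#' thresholdValue(thresholdField(f, 0.5))  # 0.015
#' @export
thresholdField <- function(field, fraction = 0.5, labels = NULL) {
  stopifnot(is(field, "FieldVector"))
  if (!is.finite(fraction) || fraction <= 0 || fraction >= 1)
    stop("fraction must lie strictly between 0 and 1")
  ids <- field@nodeId
  vals <- field@values
  if (!is.null(labels)) {
    stopifnot(is(labels, "AtlasLabelTable"))
    keep <- ids %in% labels@nodeId
    if (!any(keep)) stop("no labelled nodes in the field")
    ids <- ids[keep]; vals <- vals[keep]
  }
  mx <- max(vals)
  if (mx <= 0) stop("cannot threshold an all-zero field")
  thr <- fraction * mx
  sel <- vals > thr
  new("ThresholdedSet", montageName = field@montageName,
      fraction = as.numeric(fraction), threshold = thr,
      nodeId = ids[sel], nAbove = as.integer(sum(sel)))
}

#' Number of nodes common to two above-threshold sets
#'
#' Overlap is computed by node-identifier intersection, which assumes both
#' fields were simulated on the same head model (shared node identifiers).
#' Symmetric in its arguments.
#'
#' @param a,b [ThresholdedSet-class] objects.
#' @return Integer intersection size.
#' @export
countOverlap <- function(a, b) {
  stopifnot(is(a, "ThresholdedSet"), is(b, "ThresholdedSet"))
  length(intersect(a@nodeId, b@nodeId))
}

#' Overlap proportion p = N_overlap / N_above
#'
#' By the convention of the pairwise tables, `nAbove` is the above-threshold
#' count of the first (dorsal) montage of the pair. An overlap of zero returns
#' `p = 0` with a note (the strict `p > 0` qualifier of the defining formula
#' is relaxed at the boundary).
#'
#' @param nOverlap number of overlapping above-threshold nodes.
#' @param nAbove above-threshold count of the first montage (must be > 0).
#' @return The proportion `p`.
#' @examples
#' overlapProportion(903, 1695)  # 0.53 at 2 dp
#' @export
overlapProportion <- function(nOverlap, nAbove) {
  if (!is.finite(nAbove) || nAbove <= 0) stop("nAbove must be positive")
  if (!is.finite(nOverlap) || nOverlap < 0) stop("nOverlap must be non-negative")
  if (nOverlap > nAbove) stop("nOverlap cannot exceed nAbove")
  if (nOverlap == 0)
    message("overlap is zero; returning p = 0 (boundary convention)")
  nOverlap / nAbove
}

#' Contrast ratio r = |p1 - p2| / (p1 + p2)
#'
#' Bounded in [0, 1], symmetric, zero iff the two proportions are equal, and
#' approaching 1 as one proportion vanishes relative to the other. Used to
#' judge whether a change (electrode size, cathode position) altered the
#' overlap proportion.
#'
#' @param p1,p2 non-negative overlap proportions, not both zero.
#' @return A list of class `mscopePairComparison` with `p1`, `p2` and `r`
#'   (full precision; round to 2 decimals for table-style reporting).
#' @examples
#' pairRatio(903 / 1695, 213 / 1092)$r  # 0.46 at 2 dp
#' @export
pairRatio <- function(p1, p2) {
  if (!is.finite(p1) || !is.finite(p2) || p1 < 0 || p2 < 0)
    stop("p1 and p2 must be finite and non-negative")
  if (p1 + p2 == 0) stop("r is undefined when p1 + p2 = 0")
  out <- list(p1 = p1, p2 = p2, r = abs(p1 - p2) / (p1 + p2))
  class(out) <- "mscopePairComparison"
  out
}

#' @export
print.mscopePairComparison <- function(x, ...) {
  cat(sprintf("p1 = %.2f, p2 = %.2f, r = %.2f\n", x$p1, x$p2, x$r))
  invisible(x)
}

#' All dorsal x ventral overlap results
#'
#' Evaluates every combination of dorsal and ventral above-threshold sets
#' (e.g. all 25 combinations of 5 dorsal and 5 ventral montages), computing
#' the overlap count and the proportion `p` with the dorsal montage's count as
#' denominator.
#'
#' @param dorsal,ventral lists of [ThresholdedSet-class] objects.
#' @return A data.frame with one row per pair: `dorsal`, `ventral`,
#'   `nAboveDorsal`, `nAboveVentral`, `nOverlap`, `p`.
#' @export
allPairsOverlap <- function(dorsal, ventral) {
  if (length(dorsal) == 0L || length(ventral) == 0L)
    stop("both montage lists must be non-empty")
  rows <- list()
  for (a in dorsal) for (b in ventral) {
    nov <- countOverlap(a, b)
    rows[[length(rows) + 1L]] <- data.frame(
      dorsal = a@montageName, ventral = b@montageName,
      nAboveDorsal = a@nAbove, nAboveVentral = b@nAbove,
      nOverlap = nov, p = nov / a@nAbove,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
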