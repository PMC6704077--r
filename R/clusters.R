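# Gyrus clustering of above-threshold nodes: clusters are anatomical
# (hemisphere, gyrus) groups, ranked by CMCD -- the *sum* of member field
# values, so cluster extent and intensity both contribute.

#' Cluster above-threshold nodes by gyrus and rank by CMCD
#'
#' Groups the above-threshold nodes of a montage by (hemisphere, gyrus) and
#' computes each cluster's CMCD (total field value over member nodes).
#' Clusters are sorted by descending CMCD with alphabetical tie-breaks on the
#' gyrus label (then hemisphere) and ranked 1..Cn. Clustering is purely by
#' anatomical label, not spatial contiguity.
#'
#' @param thresholded a [ThresholdedSet-class] whose node identifiers are all
#'   labelled.
#' @param field the [FieldVector-class] the set was derived from.
#' @param labels an [AtlasLabelTable-class].
#' @return A data.frame with columns `hemisphere`, `gyrus`, `nNodes`, `cmcd`,
#'   `rank`; zero rows when the thresholded set is empty.
#' @export
clusterByGyrus <- function(thresholded, field, labels) {
  stopifnot(is(thresholded, "ThresholdedSet"), is(field, "FieldVector"),
            is(labels, "AtlasLabelTable"))
  empty <- data.frame(hemisphere = character(0), gyrus = character(0),
                      nNodes = integer(0), cmcd = numeric(0),
                      rank = integer(0), stringsAsFactors = FALSE)
  if (thresholded@nAbove == 0L) return(empty)
  ids <- thresholded@nodeId
  li <- match(ids, labels@nodeId)
  if (anyNA(li))
    stop("thresholded set contains unlabelled node(s)")
  fi <- match(ids, field@nodeId)
  if (anyNA(fi))
    stop("thresholded set contains node(s) absent from the field")
  key <- paste(labels@hemisphere[li], labels@gyrus[li], sep = "\t")
  cmcd <- tapply(field@values[fi], key, sum)
  nn <- tapply(field@values[fi], key, length)
  parts <- do.call(rbind, strsplit(names(cmcd), "\t", fixed = TRUE))
  out <- data.frame(hemisphere = parts[, 1], gyrus = parts[, 2],
                    nNodes = as.integer(nn), cmcd = unname(cmcd),
                    stringsAsFactors = FALSE)
  ord <- order(-out$cmcd, out$gyrus, out$hemisphere)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Top-k clusters by CMCD rank
#'
#' @param clusters a cluster table from [clusterByGyrus()].
#' @param k number of clusters to keep (at least 1); when `k` exceeds the
#'   number of clusters, all are returned.
#' @return The first `min(k, Cn)` rows of `clusters`.
#' @export
topClusters <- function(clusters, k) {
  if (!is.finite(k) || k < 1) stop("k must be at least 1")
  utils::head(clusters[order(clusters$rank), , drop = FALSE], n = as.integer(k))
}
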