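# The three-principle montage-selection procedure:
#   1. lobe selectivity screening (max_MCD at the target lobe, minimal spread)
#   2. least pairwise overlap between a dorsal and a ventral montage
#   3. verification that target gyri carry top-ranked CMCD clusters

#' Selection targets for the three-principle procedure
#'
#' Defaults encode the reading-pathway targets: the dorsal (grapho-
#' phonological) route aims at the left parietal lobe with the supramarginal
#' gyrus as focus, the ventral (lexico-semantic) route at the left temporal
#' lobe with the middle/inferior temporal gyri as focus.
#'
#' @param dorsalLobe,ventralLobe length-2 character `c(hemisphere, lobe)`.
#' @param dorsalGyri,ventralGyri character vectors of target gyrus labels.
#' @param topK how many top CMCD clusters principle 3 inspects.
#' @return A list of class `mscopeTargets`.
#' @export
selectionTargets <- function(dorsalLobe = c("left", "parietal"),
                             dorsalGyri = "Supramarginal Gyrus",
                             ventralLobe = c("left", "temporal"),
                             ventralGyri = c("Middle Temporal Gyrus",
                                             "Inferior Temporal Gyrus"),
                             topK = 5L) {
  stopifnot(length(dorsalLobe) == 2L, length(ventralLobe) == 2L,
            length(dorsalGyri) >= 1L, length(ventralGyri) >= 1L, topK >= 1L)
  out <- list(dorsalLobe = dorsalLobe, dorsalGyri = dorsalGyri,
              ventralLobe = ventralLobe, ventralGyri = ventralGyri,
              topK = as.integer(topK))
  class(out) <- "mscopeTargets"
  out
}

#' Principle 1: lobe selectivity screening
#'
#' Keeps montages whose max_MCD lobe is the target category, excluding those
#' whose maximum is shared with another lobe within relative tolerance
#' `sharedMaxTol` (montages that would comparably stimulate two lobes).
#' Survivors are ranked by ascending spread count, then by ascending total
#' exceedance mass of non-target lobes, then alphabetically.
#'
#' @param statsList named list of [LobeStats-class], one per montage.
#' @param target length-2 character `c(hemisphere, lobe)`.
#' @param sharedMaxTol relative tolerance for declaring a shared maximum.
#' @return A list with `table` (per-montage screening data.frame) and
#'   `survivors` (ranked character vector of montage names; may be empty).
#' @export
principle1Screen <- function(statsList, target, sharedMaxTol = 1e-6) {
  stopifnot(length(statsList) >= 1L)
  if (is.null(names(statsList)))
    names(statsList) <- vapply(statsList, montageName, character(1))
  targetKey <- .categoryKey(target[1], target[2])
  rows <- lapply(names(statsList), function(nm) {
    s <- statsList[[nm]]
    means <- s@perLobe$mean
    keys <- .categoryKey(s@perLobe$hemisphere, s@perLobe$lobe)
    iMax <- which.max(means)
    shared <- sum(means >= s@maxValue * (1 - sharedMaxTol)) > 1L
    nonTargetExceed <- sum(s@exceedance[names(s@exceedance) != targetKey])
    data.frame(montage = nm, maxCategory = keys[iMax],
               atTarget = identical(keys[iMax], targetKey),
               sharedMax = shared, spreadCount = s@spreadCount,
               nonTargetExceedance = nonTargetExceed,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  surv <- tab[tab$atTarget & !tab$sharedMax, , drop = FALSE]
  surv <- surv[order(surv$spreadCount, surv$nonTargetExceedance, surv$montage), ,
               drop = FALSE]
  list(table = tab, survivors = surv$montage)
}

#' Principle 2: pair with least overlap
#'
#' Picks the montage pair with minimal `nOverlap` from a pairwise overlap
#' table, with a deterministic lexicographic tie-break on (dorsal, ventral)
#' names; ties are flagged.
#'
#' @param pairTable data.frame from [allPairsOverlap()].
#' @return A list with `winner` (`c(dorsal, ventral)`), `nOverlap`, `p` and
#'   `tied`.
#' @export
principle2BestPair <- function(pairTable) {
  if (is.null(pairTable) || nrow(pairTable) == 0L)
    stop("empty overlap table")
  mn <- min(pairTable$nOverlap)
  cand <- pairTable[pairTable$nOverlap == mn, , drop = FALSE]
  cand <- cand[order(cand$dorsal, cand$ventral), , drop = FALSE]
  list(winner = c(cand$dorsal[1], cand$ventral[1]),
       nOverlap = as.integer(mn), p = cand$p[1], tied = nrow(cand) > 1L)
}

#' Principle 3: verify target gyri among top clusters
#'
#' A montage is verified when at least one of its target gyri appears among
#' the `topK` clusters by CMCD; the outcome lists which target gyri were found
#' and at what rank.
#'
#' @param clusters cluster table from [clusterByGyrus()].
#' @param targetGyri character vector of target gyrus labels.
#' @param topK how many top clusters to inspect.
#' @return A list with `verified`, `found` (data.frame `gyrus`, `rank`) and
#'   `topK`.
#' @export
principle3Verify <- function(clusters, targetGyri, topK = 5L) {
  if (!is.finite(topK) || topK < 1) stop("topK must be at least 1")
  top <- topClusters(clusters, topK)
  hit <- top[top$gyrus %in% targetGyri, , drop = FALSE]
  list(verified = nrow(hit) > 0L,
       found = data.frame(gyrus = hit$gyrus, rank = hit$rank,
                          stringsAsFactors = FALSE),
       topK = as.integer(topK))
}

#' Run the full three-principle selection
#'
#' Applies principles 1-3 in order to a set of dorsal- and ventral-pathway
#' fields: per-montage lobe selectivity screening against each pathway's
#' target lobe, least thresholded overlap across montage pairs, and
#' top-cluster verification of the winning pair's target gyri. The final pair
#' is the principle-2 winner when both members survive principle 1 and pass
#' principle 3; otherwise the report explains the failure and the final pair
#' is `"none"`.
#'
#' `pairScope` controls which pairs principle 2 evaluates: `"winnerRow"`
#' (default) fixes the dorsal side to the top-ranked principle-1 survivor and
#' compares every ventral montage against it, the procedure used to settle a
#' dorsal winner first and then pick its least-overlapping ventral partner;
#' `"survivors"` evaluates all survivor x survivor pairs; `"all"` evaluates
#' the complete dorsal x ventral matrix.
#'
#' @param dorsalFields,ventralFields named lists of [FieldVector-class]
#'   objects (names are montage names).
#' @param labels an [AtlasLabelTable-class].
#' @param targets a [selectionTargets()] list.
#' @param fraction threshold fraction for principle 2 (default 0.5).
#' @param pairScope `"winnerRow"`, `"survivors"` or `"all"`.
#' @return A [SelectionReport-class].
#' @export
selectMontages <- function(dorsalFields, ventralFields, labels,
                           targets = selectionTargets(), fraction = 0.5,
                           pairScope = c("winnerRow", "survivors", "all")) {
  pairScope <- match.arg(pairScope)
  stopifnot(length(dorsalFields) >= 1L, length(ventralFields) >= 1L)
  if (is.null(names(dorsalFields)))
    names(dorsalFields) <- vapply(dorsalFields, montageName, character(1))
  if (is.null(names(ventralFields)))
    names(ventralFields) <- vapply(ventralFields, montageName, character(1))

  dorsalStats <- lapply(dorsalFields, lobeStatistics, labels = labels)
  ventralStats <- lapply(ventralFields, lobeStatistics, labels = labels)
  p1d <- principle1Screen(dorsalStats, targets$dorsalLobe)
  p1v <- principle1Screen(ventralStats, targets$ventralLobe)
  principle1 <- list(dorsal = p1d$table, ventral = p1v$table,
                     survivors = list(dorsal = p1d$survivors,
                                      ventral = p1v$survivors),
                     stats = c(dorsalStats, ventralStats))

  dSets <- lapply(dorsalFields, thresholdField, fraction = fraction,
                  labels = labels)
  vSets <- lapply(ventralFields, thresholdField, fraction = fraction,
                  labels = labels)
  if (pairScope == "winnerRow") {
    dEval <- dSets[utils::head(p1d$survivors, 1)]
    vEval <- vSets
  } else if (pairScope == "survivors") {
    dEval <- dSets[p1d$survivors]
    vEval <- vSets[p1v$survivors]
  } else {
    dEval <- dSets
    vEval <- vSets
  }

  principle2 <- list(pairScope = pairScope)
  principle3 <- list()
  finalPair <- "none"
  reason <- NULL
  if (length(dEval) == 0L || length(vEval) == 0L) {
    reason <- "no montage survived the lobe selectivity screening"
    principle2$pairs <- NULL
  } else {
    pairs <- allPairsOverlap(dEval, vEval)
    best <- principle2BestPair(pairs)
    principle2$pairs <- pairs
    principle2$winner <- best$winner
    principle2$nOverlap <- best$nOverlap
    principle2$p <- best$p
    principle2$tied <- best$tied

    wd <- best$winner[1]; wv <- best$winner[2]
    allFields <- c(dorsalFields, ventralFields)
    allSets <- c(dSets, vSets)
    cd <- clusterByGyrus(allSets[[wd]], allFields[[wd]], labels)
    cv <- clusterByGyrus(allSets[[wv]], allFields[[wv]], labels)
    vd <- principle3Verify(cd, targets$dorsalGyri, targets$topK)
    vv <- principle3Verify(cv, targets$ventralGyri, targets$topK)
    principle3 <- list(dorsal = c(list(montage = wd, clusters = cd), vd),
                       ventral = c(list(montage = wv, clusters = cv), vv))

    surviveBoth <- (wd %in% p1d$survivors) && (wv %in% p1v$survivors)
    if (!surviveBoth) {
      reason <- "principle-2 winner not among principle-1 survivors"
    } else if (!vd$verified || !vv$verified) {
      reason <- sprintf(
        "top-%d cluster verification failed for: %s", targets$topK,
        paste(c(wd, wv)[!c(vd$verified, vv$verified)], collapse = ", "))
    } else {
      finalPair <- c(wd, wv)
    }
  }
  if (!is.null(reason)) principle3$failureReason <- reason
  new("SelectionReport", principle1 = principle1, principle2 = principle2,
      principle3 = principle3, finalPair = finalPair,
      targets = unclass(targets))
}
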