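# Sensitivity analysis: 1 cm electrode displacement on the scalp and total
# current halving (2 mA -> 1 mA), reported as their effect on the lobe
# selectivity configuration.

#' Displace a scalp electrode by a fixed geodesic distance
#'
#' Returns the four positions obtained by moving a scalp site `distanceMm`
#' along the great circles through the local superior-inferior and
#' anterior-posterior tangent directions ("1 cm up/down in the coronal plane,
#' left/right in the axial plane"), re-projected onto the scalp sphere. At the
#' vertex, where those tangent directions degenerate, a fixed fallback frame
#' (the x and y axes) is used.
#'
#' @param siteCoord length-3 scalp coordinate (mm), assumed on the sphere.
#' @param headRadius scalp sphere radius (mm).
#' @param distanceMm geodesic displacement in mm (default 10).
#' @return A 4 x 3 matrix with rows `superior`, `inferior`, `anterior`,
#'   `posterior`.
#' @export
perturbElectrode <- function(siteCoord, headRadius, distanceMm = 10) {
  stopifnot(length(siteCoord) == 3L, headRadius > 0)
  n <- .unit(as.numeric(siteCoord))
  proj <- function(axis) axis - sum(axis * n) * n
  tSup <- proj(c(0, 0, 1)); tAnt <- proj(c(0, 1, 0))
  if (sqrt(sum(tSup^2)) < 1e-8 || sqrt(sum(tAnt^2)) < 1e-8) {
    tSup <- proj(c(0, 1, 0)); tAnt <- proj(c(1, 0, 0))  # pole fallback frame
  }
  tSup <- .unit(tSup); tAnt <- .unit(tAnt)
  alpha <- distanceMm / headRadius
  rot <- function(t) headRadius * (cos(alpha) * n + sin(alpha) * t)
  out <- rbind(superior = rot(tSup), inferior = rot(-tSup),
               anterior = rot(tAnt), posterior = rot(-tAnt))
  colnames(out) <- c("x", "y", "z")
  out
}

.replaceSite <- function(layout, label, coord) {
  pos <- layout@positions
  pos[label, ] <- coord
  new("ElectrodeLayout", positions = pos, headRadius = layout@headRadius)
}

.lobeMeans <- function(stats) {
  stats::setNames(stats@perLobe$mean,
                  .categoryKey(stats@perLobe$hemisphere, stats@perLobe$lobe))
}

#' Electrode-displacement sensitivity
#'
#' Simulates the montage at its nominal electrode positions and at the eight
#' variants obtained by displacing the anode and the cathode 1 cm (default)
#' in each of the four tangent directions, and reports per-lobe mean deltas
#' and whether the max_MCD lobe identity changes in any variant.
#'
#' @param montage a [MontageSpec-class].
#' @param cloud a [NodeCloud-class].
#' @param labels an [AtlasLabelTable-class].
#' @param layout an [ElectrodeLayout-class].
#' @param params a [SimulationParams-class].
#' @param seed noise seed passed to [simulateField()].
#' @param distanceMm displacement magnitude in mm.
#' @return A list of class `mscopeSensitivity` with `baseline`
#'   ([LobeStats-class]), `variants` (per-perturbation description, stats,
#'   `maxLobeChanged`, per-lobe `deltas`) and `anyMaxLobeChanged`.
#' @export
displacementSensitivity <- function(montage, cloud, labels, layout,
                                    params = SimulationParams(), seed = 1L,
                                    distanceMm = 10) {
  base <- simulateField(montage, cloud, layout, params, seed = seed)
  baseStats <- lobeStatistics(base, labels)
  baseMeans <- .lobeMeans(baseStats)
  variants <- list()
  for (role in c("anode", "cathode")) {
    site <- slot(montage, role)
    disp <- perturbElectrode(sitePosition(layout, site), layout@headRadius,
                             distanceMm)
    for (dir in rownames(disp)) {
      lay2 <- .replaceSite(layout, site, disp[dir, ])
      f <- simulateField(montage, cloud, lay2, params, seed = seed)
      s <- lobeStatistics(f, labels)
      m <- .lobeMeans(s)
      common <- intersect(names(baseMeans), names(m))
      variants[[paste(role, dir, sep = "_")]] <- list(
        description = sprintf("%s displaced %g mm %s", site, distanceMm, dir),
        stats = s,
        maxLobeChanged = !identical(maxLobe(s), maxLobe(baseStats)),
        deltas = m[common] - baseMeans[common])
    }
  }
  out <- list(montage = formatMontageName(montage), mode = "displacement",
              baseline = baseStats, variants = variants,
              anyMaxLobeChanged = any(vapply(variants, `[[`, logical(1),
                                             "maxLobeChanged")))
  class(out) <- "mscopeSensitivity"
  out
}

#' Current-intensity sensitivity
#'
#' Simulates the montage at two total currents (default 2 mA and 1 mA).
#' With noise off the field is strictly linear in the current, so every
#' per-lobe mean at 1 mA is exactly half its 2 mA value and all scale-free
#' statistics (threshold-set membership, p, r, cluster ranks, max_MCD lobe)
#' are unchanged; the result reports the achieved per-lobe ratios and whether
#' the above-threshold sets agree. With noise on and several seeds, a paired
#' t-test on per-(lobe, seed) means quantifies the intensity effect.
#'
#' @param montage a [MontageSpec-class].
#' @param cloud,labels,layout,params as in [displacementSensitivity()].
#' @param currents length-2 numeric, high then low intensity in mA.
#' @param seeds integer vector of noise seeds (one per replicate).
#' @return A list of class `mscopeSensitivity` with `baseline`, per-lobe
#'   `means` at each current, `ratios`, `thresholdSetsIdentical`,
#'   `maxLobeChanged`, and (when replicated) `pairedTest`.
#' @export
intensitySensitivity <- function(montage, cloud, labels, layout,
                                 params = SimulationParams(),
                                 currents = c(2, 1), seeds = 1L) {
  stopifnot(length(currents) == 2L, all(currents > 0))
  runAt <- function(current, seed) {
    m <- MontageSpec(montage@anode, montage@cathode, montage@sizeL,
                     montage@sizeB, current)
    simulateField(m, cloud, layout, params, seed = seed)
  }
  hiMeans <- list(); loMeans <- list()
  for (s in seeds) {
    hiMeans[[as.character(s)]] <- .lobeMeans(lobeStatistics(runAt(currents[1], s), labels))
    loMeans[[as.character(s)]] <- .lobeMeans(lobeStatistics(runAt(currents[2], s), labels))
  }
  fHi <- runAt(currents[1], seeds[1]); fLo <- runAt(currents[2], seeds[1])
  sHi <- lobeStatistics(fHi, labels); sLo <- lobeStatistics(fLo, labels)
  tHi <- thresholdField(fHi, labels = labels)
  tLo <- thresholdField(fLo, labels = labels)
  out <- list(montage = formatMontageName(montage), mode = "intensity",
              currents = currents,
              baseline = sHi,
              means = list(high = hiMeans[[1]], low = loMeans[[1]]),
              ratios = loMeans[[1]] / hiMeans[[1]],
              thresholdSetsIdentical = setequal(tHi@nodeId, tLo@nodeId),
              maxLobeChanged = !identical(maxLobe(sHi), maxLobe(sLo)))
  if (length(seeds) > 1L) {
    hi <- unlist(hiMeans); lo <- unlist(loMeans)
    tt <- stats::t.test(hi, lo, paired = TRUE)
    out$pairedTest <- list(tStat = unname(tt$statistic),
                           df = unname(tt$parameter),
                           pValue = tt$p.value,
                           meanDelta = unname(tt$estimate),
                           direction = if (unname(tt$estimate) > 0)
                             "decrease at lower current" else
                             "no decrease")
  }
  class(out) <- "mscopeSensitivity"
  out
}

#' @export
print.mscopeSensitivity <- function(x, ...) {
  cat(sprintf("Sensitivity analysis (%s) for %s\n", x$mode, x$montage))
  if (x$mode == "displacement") {
    cat(sprintf("  variants: %d; max_MCD lobe changed in any: %s\n",
                length(x$variants), x$anyMaxLobeChanged))
  } else {
    cat(sprintf("  currents: %g mA vs %g mA; per-lobe mean ratio range [%.3f, %.3f]\n",
                x$currents[1], x$currents[2], min(x$ratios), max(x$ratios)))
    cat(sprintf("  threshold sets identical: %s; max_MCD lobe changed: %s\n",
                x$thresholdSetsIdentical, x$maxLobeChanged))
    if (!is.null(x$pairedTest))
      cat(sprintf("  paired test: t = %.3f, p = %.3g (%s)\n",
                  x$pairedTest$tStat, x$pairedTest$pValue,
                  x$pairedTest$direction))
  }
  invisible(x)
}
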