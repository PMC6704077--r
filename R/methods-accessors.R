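#' @rdname NodeCloud-class
setMethod("nodeIds", "NodeCloud", function(object) object@nodeId)

#' @rdname NodeCloud-class
setMethod("nodeCoords", "NodeCloud", function(object) object@coords)

#' @rdname NodeCloud-class
setMethod("coordSpace", "NodeCloud", function(object) object@space)

#' @rdname FieldVector-class
setMethod("nodeIds", "FieldVector", function(object) object@nodeId)

#' @rdname FieldVector-class
setMethod("fieldValues", "FieldVector", function(object) {
  stats::setNames(object@values, object@nodeId)
})

#' @rdname FieldVector-class
setMethod("fieldKind", "FieldVector", function(object) object@kind)

#' @rdname FieldVector-class
setMethod("montageName", "FieldVector", function(object) object@montageName)

#' @rdname AtlasLabelTable-class
setMethod("nodeIds", "AtlasLabelTable", function(object) object@nodeId)

#' @rdname AtlasLabelTable-class
setMethod("labelTable", "AtlasLabelTable", function(object) {
  data.frame(node_id = object@nodeId, hemisphere = object@hemisphere,
             lobe = object@lobe, gyrus = object@gyrus,
             stringsAsFactors = FALSE)
})

#' @describeIn MontageSpec-class canonical `X_Y_L_B` name of the montage.
setMethod("montageName", "MontageSpec", function(object) {
  formatMontageName(object)
})

#' @rdname LobeStats-class
setMethod("perLobeTable", "LobeStats", function(object) object@perLobe)

#' @rdname LobeStats-class
setMethod("maxLobe", "LobeStats", function(object) object@maxLobe)

#' @rdname LobeStats-class
setMethod("avgAcrossLobes", "LobeStats", function(object) object@avgAcrossLobes)

#' @rdname LobeStats-class
setMethod("exceedanceProfile", "LobeStats", function(object) object@exceedance)

#' @rdname LobeStats-class
setMethod("spreadCount", "LobeStats", function(object) object@spreadCount)

#' @rdname LobeStats-class
setMethod("montageName", "LobeStats", function(object) object@montageName)

#' @rdname ThresholdedSet-class
setMethod("thresholdValue", "ThresholdedSet", function(object) object@threshold)

#' @rdname ThresholdedSet-class
setMethod("aboveThresholdIds", "ThresholdedSet", function(object) object@nodeId)

#' @rdname ThresholdedSet-class
setMethod("nAbove", "ThresholdedSet", function(object) object@nAbove)

#' @rdname ThresholdedSet-class
setMethod("montageName", "ThresholdedSet", function(object) object@montageName)

#' @rdname SelectionReport-class
setMethod("finalPair", "SelectionReport", function(object) object@finalPair)

#' @rdname ElectrodeLayout-class
setMethod("sitePosition", "ElectrodeLayout", function(object, label) {
  if (!label %in% rownames(object@positions))
    stop("unknown electrode site: ", label)
  object@positions[label, ]
})

# show() methods ---------------------------------------------------------

setMethod("show", "NodeCloud", function(object) {
  cat(sprintf("NodeCloud: %d nodes in %s space (mm)\n",
              length(object@nodeId), object@space))
  rng <- apply(object@coords, 2, range)
  cat(sprintf("  x: [%.1f, %.1f]  y: [%.1f, %.1f]  z: [%.1f, %.1f]\n",
              rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]))
})

setMethod("show", "FieldVector", function(object) {
  cat(sprintf("FieldVector (%s) for montage '%s': %d nodes\n",
              object@kind, object@montageName, length(object@nodeId)))
  cat(sprintf("  values: max %.4g, mean %.4g\n",
              max(object@values), mean(object@values)))
})

setMethod("show", "AtlasLabelTable", function(object) {
  cat(sprintf("AtlasLabelTable: %d labelled nodes, %d (hemisphere, lobe) categories, %d gyri\n",
              length(object@nodeId),
              nrow(unique(data.frame(object@hemisphere, object@lobe))),
              length(unique(object@gyrus))))
})

setMethod("show", "MontageSpec", function(object) {
  cat(sprintf("MontageSpec %s: anode %s, cathode %s, %g x %g cm^2, %g mA\n",
              formatMontageName(object), object@anode, object@cathode,
              object@sizeL, object@sizeB, object@current))
})

setMethod("show", "ElectrodeLayout", function(object) {
  cat(sprintf("ElectrodeLayout: %d sites on a %g mm head sphere\n",
              nrow(object@positions), object@headRadius))
  cat("  sites:", paste(rownames(object@positions), collapse = ", "), "\n")
})

setMethod("show", "SimulationParams", function(object) {
  cat(sprintf(paste0("SimulationParams: sigma0 %g mm, spread exp %g, gain exp %g, ",
                     "leak %g, path sigma %g mm, noise sd %g, seed %d\n"),
              object@sigma0, object@sizeSpreadExponent, object@peakGainExponent,
              object@leakFraction, object@pathSigma, object@noiseSd, object@seed))
})

setMethod("show", "LobeStats", function(object) {
  cat(sprintf("LobeStats for '%s'\n", object@montageName))
  cat(sprintf("  max_MCD lobe: %s %s (mean %.4g); avg_MCD %.4g; spread count %d\n",
              object@maxLobe[1], object@maxLobe[2], object@maxValue,
              object@avgAcrossLobes, object@spreadCount))
  if (length(object@exceedance)) {
    cat("  exceedance (%):\n")
    for (nm in names(object@exceedance))
      cat(sprintf("    %s: %.1f\n", nm, object@exceedance[[nm]]))
  }
})

setMethod("show", "ThresholdedSet", function(object) {
  cat(sprintf("ThresholdedSet '%s': %d nodes above %.4g (%.0f%% of max)\n",
              object@montageName, object@nAbove, object@threshold,
              100 * object@fraction))
})

setMethod("show", "SelectionReport", function(object) {
  cat("SelectionReport\n")
  surv <- object@principle1$survivors
  cat(sprintf("  principle 1 survivors: dorsal [%s]; ventral [%s]\n",
              paste(surv$dorsal, collapse = ", "),
              paste(surv$ventral, collapse = ", ")))
  if (!is.null(object@principle2$winner))
    cat(sprintf("  principle 2 winner: %s & %s (n_overlap = %d)\n",
                object@principle2$winner[1], object@principle2$winner[2],
                object@principle2$nOverlap))
  cat(sprintf("  final pair: %s\n", paste(object@finalPair, collapse = " & ")))
})
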