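# Accessor generics. Slot access from user code is discouraged; these are the
# supported surface.

#' @rdname NodeCloud-class
#' @param object an object of the documented class.
#' @export
setGeneric("nodeIds", function(object) standardGeneric("nodeIds"))

#' @rdname NodeCloud-class
#' @export
setGeneric("nodeCoords", function(object) standardGeneric("nodeCoords"))

#' @rdname NodeCloud-class
#' @export
setGeneric("coordSpace", function(object) standardGeneric("coordSpace"))

#' @rdname FieldVector-class
#' @param object an object of the documented class.
#' @export
setGeneric("fieldValues", function(object) standardGeneric("fieldValues"))

#' @rdname FieldVector-class
#' @export
setGeneric("fieldKind", function(object) standardGeneric("fieldKind"))

#' @rdname FieldVector-class
#' @export
setGeneric("montageName", function(object) standardGeneric("montageName"))

#' @rdname AtlasLabelTable-class
#' @param object an object of the documented class.
#' @export
setGeneric("labelTable", function(object) standardGeneric("labelTable"))

#' @rdname LobeStats-class
#' @param object an object of the documented class.
#' @export
setGeneric("perLobeTable", function(object) standardGeneric("perLobeTable"))

#' @rdname LobeStats-class
#' @export
setGeneric("maxLobe", function(object) standardGeneric("maxLobe"))

#' @rdname LobeStats-class
#' @export
setGeneric("avgAcrossLobes", function(object) standardGeneric("avgAcrossLobes"))

#' @rdname LobeStats-class
#' @export
setGeneric("exceedanceProfile", function(object) standardGeneric("exceedanceProfile"))

#' @rdname LobeStats-class
#' @export
setGeneric("spreadCount", function(object) standardGeneric("spreadCount"))

#' @rdname ThresholdedSet-class
#' @param object an object of the documented class.
#' @export
setGeneric("thresholdValue", function(object) standardGeneric("thresholdValue"))

#' @rdname ThresholdedSet-class
#' @export
setGeneric("aboveThresholdIds", function(object) standardGeneric("aboveThresholdIds"))

#' @rdname ThresholdedSet-class
#' @export
setGeneric("nAbove", function(object) standardGeneric("nAbove"))

#' @rdname SelectionReport-class
#' @param object an object of the documented class.
#' @export
setGeneric("finalPair", function(object) standardGeneric("finalPair"))

#' @rdname ElectrodeLayout-class
#' @param object an object of the documented class.
#' @param label electrode-site label (e.g. `"CP5"`).
#' @export
setGeneric("sitePosition", function(object, label) standardGeneric("sitePosition"))
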