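#' @import methods
NULL

.SPACES <- c("native", "talairach")
.FIELD_KINDS <- c("MCD", "MEF")
.HEMISPHERES <- c("left", "right")
.LOBES <- c("frontal", "parietal", "temporal", "occipital", "limbic", "sublobar")

#' NodeCloud: per-node cortical coordinates
#'
#' A set of cortical nodes with stable integer identifiers and 3D positions in
#' millimetres, tagged with the coordinate space they live in (`"native"` head
#' space as emitted by a field simulator, or `"talairach"` atlas space).
#'
#' @slot nodeId integer vector of unique node identifiers.
#' @slot coords numeric matrix with one row per node and columns `x`, `y`, `z`
#'   (mm). Convention: RAS with the left hemisphere at `x < 0`.
#' @slot space either `"native"` or `"talairach"`.
#'
#' @seealso [NodeCloud()], [readNodeCloud()], [mapToAtlasSpace()]
#' @export
setClass("NodeCloud",
  representation(nodeId = "integer", coords = "matrix", space = "character"))

setValidity("NodeCloud", function(object) {
  n <- length(object@nodeId)
  if (n == 0L) return("a NodeCloud must contain at least one node")
  if (anyDuplicated(object@nodeId)) return("node identifiers must be unique")
  if (anyNA(object@nodeId)) return("node identifiers must not be NA")
  if (!is.numeric(object@coords)) return("coords must be numeric")
  if (nrow(object@coords) != n || ncol(object@coords) != 3L)
    return("coords must be an n x 3 matrix aligned to nodeId")
  if (!all(is.finite(object@coords))) return("coords must be finite")
  if (!identical(colnames(object@coords), c("x", "y", "z")))
    return("coords columns must be named x, y, z")
  if (length(object@space) != 1L || !object@space %in% .SPACES)
    return(sprintf("space must be one of: %s", paste(.SPACES, collapse = ", ")))
  TRUE
})

#' Construct a NodeCloud
#'
#' @param nodeId integer vector of unique node identifiers.
#' @param coords numeric n x 3 matrix of positions in mm (columns x, y, z).
#' @param space coordinate space tag, `"native"` or `"talairach"`.
#' @return A [NodeCloud-class] object.
#' @examples
#' cloud <- NodeCloud(1:3, matrix(rnorm(9), 3, 3), space = "native")
#' length(nodeIds(cloud))
#' @export
NodeCloud <- function(nodeId, coords, space = "native") {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  colnames(coords) <- c("x", "y", "z")
  rownames(coords) <- NULL
  new("NodeCloud", nodeId = as.integer(nodeId), coords = coords,
      space = as.character(space))
}

#' FieldVector: per-node scalar field values for one montage
#'
#' Magnitude of current density (MCD, simulator units) or magnitude of electric
#' field (MEF, V/m) per cortical node, aligned by node identifier to a
#' [NodeCloud-class].
#'
#' @slot nodeId integer node identifiers.
#' @slot values non-negative finite numeric vector aligned to `nodeId`.
#' @slot kind `"MCD"` or `"MEF"`.
#' @slot montageName montage the field belongs to, e.g. `"CP5_CZ_5_5"`.
#' @export
setClass("FieldVector",
  representation(nodeId = "integer", values = "numeric", kind = "character",
                 montageName = "character"))

setValidity("FieldVector", function(object) {
  if (length(object@nodeId) == 0L) return("empty field")
  if (anyDuplicated(object@nodeId)) return("node identifiers must be unique")
  if (length(object@values) != length(object@nodeId))
    return("values must align with nodeId")
  if (!all(is.finite(object@values))) return("field values must be finite")
  if (any(object@values < 0)) return("field values must be non-negative")
  if (length(object@kind) != 1L || !object@kind %in% .FIELD_KINDS)
    return(sprintf("kind must be one of: %s", paste(.FIELD_KINDS, collapse = ", ")))
  if (length(object@montageName) != 1L) return("montageName must be a single string")
  TRUE
})

#' Construct a FieldVector
#'
#' @param nodeId integer node identifiers.
#' @param values non-negative numeric field values aligned to `nodeId`.
#' @param kind `"MCD"` (default) or `"MEF"`.
#' @param montageName name of the montage the field belongs to.
#' @return A [FieldVector-class] object.
#' @export
FieldVector <- function(nodeId, values, kind = "MCD", montageName = "") {
  new("FieldVector", nodeId = as.integer(nodeId), values = as.numeric(values),
      kind = as.character(kind), montageName = as.character(montageName))
}

#' AtlasLabelTable: per-node anatomical labels
#'
#' Hemisphere, lobe and gyrus assignment per node, following the 12-category
#' (2 hemispheres x 6 lobes) parcellation used throughout the analysis.
#'
#' @slot nodeId integer node identifiers (each labelled node appears once).
#' @slot hemisphere `"left"` or `"right"` per node.
#' @slot lobe one of frontal, parietal, temporal, occipital, limbic, sublobar.
#' @slot gyrus gyrus label string per node (e.g. `"Supramarginal Gyrus"`).
#' @export
setClass("AtlasLabelTable",
  representation(nodeId = "integer", hemisphere = "character",
                 lobe = "character", gyrus = "character"))

setValidity("AtlasLabelTable", function(object) {
  n <- length(object@nodeId)
  if (n == 0L) return("empty label table")
  if (anyDuplicated(object@nodeId)) return("each node may be labelled only once")
  if (length(object@hemisphere) != n || length(object@lobe) != n ||
      length(object@gyrus) != n)
    return("hemisphere, lobe and gyrus must align with nodeId")
  if (!all(object@hemisphere %in% .HEMISPHERES))
    return("hemisphere must be 'left' or 'right'")
  if (!all(object@lobe %in% .LOBES))
    return(sprintf("lobe must be one of: %s", paste(.LOBES, collapse = ", ")))
  TRUE
})

#' Construct an AtlasLabelTable
#'
#' @param nodeId integer node identifiers.
#' @param hemisphere character vector, `"left"`/`"right"`.
#' @param lobe character vector of lobe names.
#' @param gyrus character vector of gyrus labels.
#' @return An [AtlasLabelTable-class] object.
#' @export
AtlasLabelTable <- function(nodeId, hemisphere, lobe, gyrus) {
  new("AtlasLabelTable", nodeId = as.integer(nodeId),
      hemisphere = as.character(hemisphere), lobe = as.character(lobe),
      gyrus = as.character(gyrus))
}

#' AffineTransform: homogeneous native-to-atlas mapping
#'
#' A 4 x 4 homogeneous affine taking native head-space millimetre coordinates
#' to Talairach-space millimetre coordinates.
#'
#' @slot matrix invertible 4 x 4 numeric matrix with bottom row (0, 0, 0, 1).
#' @export
setClass("AffineTransform", representation(matrix = "matrix"))

setValidity("AffineTransform", function(object) {
  m <- object@matrix
  if (!is.numeric(m) || !identical(dim(m), c(4L, 4L)))
    return("affine must be a 4 x 4 numeric matrix")
  if (!all(is.finite(m))) return("affine entries must be finite")
  if (!isTRUE(all.equal(m[4, ], c(0, 0, 0, 1))))
    return("bottom row of the affine must be (0, 0, 0, 1)")
  if (abs(det(m)) < 1e-12) return("affine must be invertible")
  TRUE
})

#' Construct an AffineTransform
#'
#' @param matrix 4 x 4 numeric matrix (native mm -> Talairach mm).
#' @return An [AffineTransform-class] object.
#' @examples
#' identityAffine <- AffineTransform(diag(4))
#' @export
AffineTransform <- function(matrix = diag(4)) {
  m <- as.matrix(matrix)
  storage.mode(m) <- "double"
  dimnames(m) <- NULL
  new("AffineTransform", matrix = m)
}

#' MontageSpec: one anode-cathode electrode configuration
#'
#' Parsed form of the `X_Y_L_B` montage naming scheme: anode site `X`, cathode
#' site `Y`, electrode dimensions `L` x `B` cm (inferior-superior by
#' anterior-posterior) and the total current in mA.
#'
#' @slot anode electrode-site label of the anode (10-10 site, e.g. `"CP5"`).
#' @slot cathode cathode site: a cephalic 10-10 site (`"CZ"`, `"CP6"`, ...),
#'   the contralateral supraorbital site `"SO_contra"`, or an extracephalic
#'   site (`"maxilla_contra"`, `"neck_nape"`).
#' @slot sizeL electrode extent along the inferior-superior axis, cm.
#' @slot sizeB electrode extent along the anterior-posterior axis, cm.
#' @slot current total current, mA.
#' @seealso [parseMontageName()], [enumerateStandardMontages()]
#' @export
setClass("MontageSpec",
  representation(anode = "character", cathode = "character",
                 sizeL = "numeric", sizeB = "numeric", current = "numeric"))

setValidity("MontageSpec", function(object) {
  if (length(object@anode) != 1L || !nzchar(object@anode))
    return("anode label required")
  if (length(object@cathode) != 1L || !nzchar(object@cathode))
    return("cathode label required")
  if (identical(object@anode, object@cathode))
    return("anode and cathode must differ")
  if (!is.finite(object@sizeL) || object@sizeL <= 0) return("sizeL must be > 0")
  if (!is.finite(object@sizeB) || object@sizeB <= 0) return("sizeB must be > 0")
  if (!is.finite(object@current) || object@current <= 0)
    return("current must be > 0")
  TRUE
})

#' Construct a MontageSpec
#'
#' @param anode anode site label.
#' @param cathode cathode site label.
#' @param sizeL,sizeB electrode dimensions in cm.
#' @param current total current in mA (default 2, the conventional intensity).
#' @return A [MontageSpec-class] object.
#' @export
MontageSpec <- function(anode, cathode, sizeL = 5, sizeB = 5, current = 2) {
  new("MontageSpec", anode = as.character(anode), cathode = as.character(cathode),
      sizeL = as.numeric(sizeL), sizeB = as.numeric(sizeB),
      current = as.numeric(current))
}

#' ElectrodeLayout: scalp coordinates of electrode sites
#'
#' Idealised spherical-head coordinates for 10-10 electrode sites plus the
#' synthetic extracephalic return sites. All cephalic sites lie on the scalp
#' sphere; extracephalic sites lie below its equator.
#'
#' @slot positions numeric k x 3 matrix (mm), rownames are site labels.
#' @slot headRadius scalp sphere radius in mm.
#' @seealso [layoutElectrodes()]
#' @export
setClass("ElectrodeLayout",
  representation(positions = "matrix", headRadius = "numeric"))

setValidity("ElectrodeLayout", function(object) {
  p <- object@positions
  if (!is.numeric(p) || ncol(p) != 3L) return("positions must be k x 3 numeric")
  if (is.null(rownames(p)) || anyDuplicated(rownames(p)))
    return("positions must have unique site-label rownames")
  if (!all(is.finite(p))) return("positions must be finite")
  if (length(object@headRadius) != 1L || object@headRadius <= 0)
    return("headRadius must be a single positive number")
  TRUE
})

#' SimulationParams: knobs of the phenomenological field generator
#'
#' Parameters of the synthetic scalar-field model: a Gaussian source centred on
#' the cortical projection of the anode plus a weighted leak term along the
#' anode-to-cathode great-circle path, with electrode-area scaling of both the
#' peak gain and the spread.
#'
#' @slot sigma0 source spread (mm) for a reference 5 x 5 cm^2 electrode.
#' @slot sizeSpreadExponent spread scales as `(area/25)^exponent`.
#' @slot peakGainExponent peak gain scales as `(25/area)^exponent`.
#' @slot leakFraction weight in `[0, 1]` of the anode-to-cathode path term.
#' @slot pathSigma Gaussian width (mm) of the path-leak kernel.
#' @slot noiseSd standard deviation of additive noise, field units.
#' @slot seed default RNG seed for the noise draw.
#' @seealso [SimulationParams()], [simulateField()]
#' @export
setClass("SimulationParams",
  representation(sigma0 = "numeric", sizeSpreadExponent = "numeric",
                 peakGainExponent = "numeric", leakFraction = "numeric",
                 pathSigma = "numeric", noiseSd = "numeric", seed = "integer"))

setValidity("SimulationParams", function(object) {
  if (!is.finite(object@sigma0) || object@sigma0 <= 0) return("sigma0 must be > 0")
  if (!is.finite(object@pathSigma) || object@pathSigma <= 0)
    return("pathSigma must be > 0")
  if (!is.finite(object@leakFraction) || object@leakFraction < 0 ||
      object@leakFraction > 1)
    return("leakFraction must lie in [0, 1]")
  if (!is.finite(object@noiseSd) || object@noiseSd < 0)
    return("noiseSd must be >= 0")
  if (!is.finite(object@sizeSpreadExponent) || !is.finite(object@peakGainExponent))
    return("exponents must be finite")
  TRUE
})

#' Construct SimulationParams
#'
#' Defaults encode the study conditions of the synthetic experiment: a 35 mm
#' source spread at the reference 5 x 5 cm^2 electrode area, square-root area
#' scaling of spread and peak, a 0.35 path-leak weight with 25 mm path kernel,
#' and noise off.
#'
#' @param sigma0 source spread in mm for a 5 x 5 cm^2 electrode.
#' @param sizeSpreadExponent exponent of the area-dependent spread law.
#' @param peakGainExponent exponent of the area-dependent peak-gain law.
#' @param leakFraction weight of the anode-to-cathode path term, in `[0, 1]`.
#' @param pathSigma width (mm) of the path-leak kernel.
#' @param noiseSd additive noise standard deviation (0 disables noise).
#' @param seed default seed used by [simulateField()] when drawing noise.
#' @return A [SimulationParams-class] object.
#' @export
SimulationParams <- function(sigma0 = 35, sizeSpreadExponent = 0.5,
                             peakGainExponent = 0.5, leakFraction = 0.35,
                             pathSigma = 25, noiseSd = 0, seed = 1L) {
  new("SimulationParams", sigma0 = as.numeric(sigma0),
      sizeSpreadExponent = as.numeric(sizeSpreadExponent),
      peakGainExponent = as.numeric(peakGainExponent),
      leakFraction = as.numeric(leakFraction),
      pathSigma = as.numeric(pathSigma), noiseSd = as.numeric(noiseSd),
      seed = as.integer(seed))
}

#' LobeStats: lobe selectivity configuration of one montage
#'
#' Per-(hemisphere, lobe) summary of a field: category means and standard
#' deviations, the category with maximum mean (max_MCD), the unweighted mean of
#' category means (avg_MCD), the exceedance profile (percent by which each
#' above-average category exceeds avg_MCD) and the spread count (non-maximum
#' categories above avg_MCD).
#'
#' @slot perLobe data.frame with columns hemisphere, lobe, n, mean, sd.
#' @slot maxLobe length-2 character, `c(hemisphere, lobe)` of the max category.
#' @slot maxValue mean of the max category.
#' @slot avgAcrossLobes unweighted mean of category means.
#' @slot exceedance named numeric, percent exceedance of above-average
#'   categories (names `"hemisphere lobe"`).
#' @slot spreadCount number of non-maximum categories above avg_MCD.
#' @slot montageName montage the statistics describe.
#' @seealso [lobeStatistics()]
#' @export
setClass("LobeStats",
  representation(perLobe = "data.frame", maxLobe = "character",
                 maxValue = "numeric", avgAcrossLobes = "numeric",
                 exceedance = "numeric", spreadCount = "integer",
                 montageName = "character"))

setValidity("LobeStats", function(object) {
  if (length(object@maxLobe) != 2L) return("maxLobe must be c(hemisphere, lobe)")
  if (object@maxValue < max(object@perLobe$mean) - 1e-12)
    return("maxValue must be the largest category mean")
  if (length(object@exceedance) && any(object@exceedance <= 0))
    return("exceedance entries must be positive")
  TRUE
})

#' ThresholdedSet: nodes above a fraction-of-maximum threshold
#'
#' The above-threshold node set of one montage under fraction-of-max
#' thresholding (default 50%), i.e. the paper-style `N > thresh` region.
#'
#' @slot montageName montage the set belongs to.
#' @slot fraction threshold fraction of the field maximum.
#' @slot threshold absolute threshold, field units.
#' @slot nodeId identifiers of nodes with value strictly above threshold.
#' @slot nAbove number of above-threshold nodes.
#' @seealso [thresholdField()], [countOverlap()]
#' @export
setClass("ThresholdedSet",
  representation(montageName = "character", fraction = "numeric",
                 threshold = "numeric", nodeId = "integer", nAbove = "integer"))

setValidity("ThresholdedSet", function(object) {
  if (object@nAbove != length(object@nodeId))
    return("nAbove must equal the number of stored node identifiers")
  if (anyDuplicated(object@nodeId)) return("node identifiers must be unique")
  if (!is.finite(object@threshold) || object@threshold < 0)
    return("threshold must be finite and non-negative")
  TRUE
})

#' SelectionReport: auditable outcome of the three-principle procedure
#'
#' @slot principle1 list with per-montage lobe screening results and the
#'   surviving, ranked candidates per pathway.
#' @slot principle2 list with the pairwise overlap table and the winning pair.
#' @slot principle3 list with per-winner top clusters and verification flags.
#' @slot finalPair length-2 character `c(dorsal, ventral)` or `"none"`.
#' @slot targets the SelectionTargets the report was produced against.
#' @seealso [selectMontages()]
#' @export
setClass("SelectionReport",
  representation(principle1 = "list", principle2 = "list", principle3 = "list",
                 finalPair = "character", targets = "list"))
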