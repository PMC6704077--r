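# Synthetic head model: a two-shell hemispheric-cap node cloud with a fixed
# angular parcellation (2 hemispheres x 6 lobes, named gyri) and an idealised
# spherical 10-10 electrode layout. The geometry convention is RAS in mm:
# +x right, +y anterior, +z superior, origin at the sphere centre; the left
# hemisphere is x < 0 (x == 0 ties go left).

.unitRows <- function(m) m / sqrt(rowSums(m^2))

.unit <- function(v) v / sqrt(sum(v^2))

# unit vector from polar angle theta (degrees from +z) and azimuth az
# (degrees from +x, counter-clockwise seen from above: +y is az 90)
.sph <- function(thetaDeg, azDeg) {
  th <- thetaDeg * pi / 180; az <- azDeg * pi / 180
  c(sin(th) * cos(az), sin(th) * sin(az), cos(th))
}

# spherical linear interpolation between unit vectors
.slerp <- function(a, b, t) {
  d <- max(-1, min(1, sum(a * b)))
  om <- acos(d)
  if (om < 1e-12) return(a)
  (sin((1 - t) * om) * a + sin(t * om) * b) / sin(om)
}

.mirrorX <- function(v) c(-v[1], v[2], v[3])

# Unit-sphere directions of the electrode sites used in the analysis.
# Cephalic sites follow the proportional 10-10 arcs (equatorial ring at 18
# degree steps, coronal and parasagittal arcs interpolated); the
# extracephalic return sites are fixed synthetic directions below the equator
# (a spherical model has no neck or face geometry).
.electrodeUnitVectors <- function() {
  CZ  <- c(0, 0, 1)
  T7  <- .sph(90, 180); TP7 <- .sph(90, 198); P7 <- .sph(90, 216)
  OZ  <- .sph(90, 270); FPZ <- .sph(90, 90)
  C3  <- .sph(45, 180); C5  <- .sph(67.5, 180)
  PZ  <- .sph(36, 270)
  P3  <- .slerp(PZ, P7, 0.5)
  P5  <- .slerp(PZ, P7, 0.75)
  CP3 <- .unit(.slerp(C3, P3, 0.5))
  CP5 <- .unit(.slerp(C5, P5, 0.5))
  SO  <- .sph(80, 72)            # right supraorbital (contralateral to CP5/TP7)
  MAX <- .sph(100, 75)           # right maxilla, below the equator
  NECK <- .sph(165, 270)         # nape of the neck, posterior-inferior
  left <- rbind(T7 = T7, TP7 = TP7, P7 = P7, C3 = C3, C5 = C5, P3 = P3,
                P5 = P5, CP3 = CP3, CP5 = CP5)
  right <- t(apply(left, 1, .mirrorX))
  rownames(right) <- c("T8", "TP8", "P8", "C4", "C6", "P4", "P6", "CP4", "CP6")
  rbind(CZ = CZ, PZ = PZ, OZ = OZ, FPZ = FPZ, left, right,
        SO_contra = SO, maxilla_contra = MAX, neck_nape = NECK)
}

.CEPHALIC_SITES <- c("CZ", "PZ", "OZ", "FPZ", "T7", "TP7", "P7", "C3", "C5",
                     "P3", "P5", "CP3", "CP5", "T8", "TP8", "P8", "C4", "C6",
                     "P4", "P6", "CP4", "CP6", "SO_contra")
.EXTRACEPHALIC_SITES <- c("maxilla_contra", "neck_nape")

#' Idealised spherical 10-10 electrode layout
#'
#' Returns scalp coordinates (mm) for the electrode sites used by the montage
#' analysis: the vertex `CZ`, the centro-/temporo-parietal sites `CP5`, `CP6`,
#' `TP7`, `TP8` and neighbours, the contralateral supraorbital site
#' `SO_contra`, and the synthetic extracephalic return sites `maxilla_contra`
#' and `neck_nape`. Cephalic sites lie exactly on the scalp sphere;
#' extracephalic sites lie on the sphere below its equator plane.
#'
#' @param headRadius scalp sphere radius in mm.
#' @return An [ElectrodeLayout-class].
#' @examples
#' layout <- layoutElectrodes(85)
#' sitePosition(layout, "CZ")   # c(0, 0, 85)
#' @export
layoutElectrodes <- function(headRadius = 85) {
  if (!is.finite(headRadius) || headRadius <= 0)
    stop("headRadius must be positive")
  u <- .electrodeUnitVectors()
  pos <- u * headRadius
  colnames(pos) <- c("x", "y", "z")
  new("ElectrodeLayout", positions = pos, headRadius = as.numeric(headRadius))
}

# Fixed angular partition assigning (hemisphere, lobe, gyrus) to a coordinate.
# Nodes on the inner shell (radius below the shell midpoint) are sublobar;
# outer-shell nodes split into a medial limbic band, an anterior-superior
# frontal sector, a posterior-superior parietal sector, a lateral-inferior
# temporal sector and a posterior-inferior occipital sector. Each lobe is
# subdivided into named gyri by further angular bands.
.partitionNodes <- function(coords, cortexRadius, innerRadius) {
  r <- sqrt(rowSums(coords^2))
  u <- coords / r
  ux <- u[, 1]; uy <- u[, 2]; uz <- pmax(-1, pmin(1, u[, 3]))
  e <- asin(uz) * 180 / pi                 # elevation, degrees
  l <- abs(ux)                             # laterality
  n <- nrow(coords)
  hemisphere <- ifelse(ux <= 0, "left", "right")
  lobe <- character(n); gyrus <- character(n)

  inner <- r < (cortexRadius + innerRadius) / 2
  lobe[inner] <- "sublobar"
  gyrus[inner] <- ifelse(l[inner] >= 0.5, "Insula", "Lentiform Nucleus")

  out <- !inner
  limbic <- out & l < 0.15 & e < 55
  lobe[limbic] <- "limbic"
  gyrus[limbic] <- ifelse(e[limbic] >= 0, "Cingulate Gyrus",
                          "Parahippocampal Gyrus")

  rest <- out & !limbic
  sup <- rest & e >= 12
  frontalSup <- sup & uy > 0.25
  parietal <- sup & !frontalSup
  inf <- rest & e < 12
  occipital <- inf & uy < -0.72
  temporal <- inf & !occipital & l >= 0.35 & uy < 0.25
  lowMedial <- inf & !occipital & !temporal
  frontalInf <- lowMedial & uy > 0
  occipital2 <- lowMedial & !frontalInf

  lobe[frontalSup | frontalInf] <- "frontal"
  lobe[parietal] <- "parietal"
  lobe[temporal] <- "temporal"
  lobe[occipital | occipital2] <- "occipital"

  i <- parietal
  gyrus[i & l >= 0.5 & uy >= -0.45] <- "Supramarginal Gyrus"
  gyrus[i & l >= 0.5 & uy < -0.45] <- "Angular Gyrus"
  gyrus[i & l >= 0.25 & l < 0.5] <- "Inferior Parietal Lobule"
  gyrus[i & l < 0.25] <- "Superior Parietal Lobule"

  i <- temporal
  gyrus[i & e >= 5] <- "Superior Temporal Gyrus"
  gyrus[i & e >= -10 & e < 5] <- "Middle Temporal Gyrus"
  gyrus[i & e >= -25 & e < -10] <- "Inferior Temporal Gyrus"
  gyrus[i & e < -25] <- "Fusiform Gyrus"

  i <- frontalInf
  gyrus[i] <- "Inferior Frontal Gyrus"
  i <- frontalSup
  gyrus[i & uy <= 0.45] <- "Precentral Gyrus"
  gyrus[i & uy > 0.45 & l >= 0.4] <- "Middle Frontal Gyrus"
  gyrus[i & uy > 0.45 & l < 0.4] <- "Superior Frontal Gyrus"

  i <- occipital | occipital2
  gyrus[i & e < 0] <- "Lingual Gyrus"
  gyrus[i & e >= 0] <- "Cuneus"

  data.frame(hemisphere = hemisphere, lobe = lobe, gyrus = gyrus,
             stringsAsFactors = FALSE)
}

#' Label a cloud with the synthetic angular partition
#'
#' Applies the head model's fixed angular parcellation to the coordinates of
#' an atlas-space cloud. Deterministic: repeated calls give identical tables.
#'
#' @param cloud a [NodeCloud-class].
#' @param cortexRadius radius (mm) of the outer (cortical) shell.
#' @param innerRadius radius (mm) of the inner (sublobar) shell.
#' @return An [AtlasLabelTable-class] covering every node of `cloud`.
#' @export
syntheticAtlasLabels <- function(cloud, cortexRadius = 0.82 * 85,
                                 innerRadius = 0.35 * 85) {
  stopifnot(is(cloud, "NodeCloud"))
  part <- .partitionNodes(nodeCoords(cloud), cortexRadius, innerRadius)
  AtlasLabelTable(nodeIds(cloud), part$hemisphere, part$lobe, part$gyrus)
}

# Fibonacci lattice on the spherical cap z/r in [sin(minElevDeg), 1]
.capLattice <- function(n, radius, minElevDeg = -40) {
  zmin <- sin(minElevDeg * pi / 180)
  i <- seq_len(n) - 0.5
  z <- zmin + (i / n) * (1 - zmin)
  phi <- i * pi * (3 - sqrt(5))            # golden angle
  s <- sqrt(pmax(0, 1 - z^2))
  cbind(x = s * cos(phi), y = s * sin(phi), z = z) * radius
}

#' Build the synthetic head model
#'
#' Generates a quasi-uniform two-shell node cloud emulating the cortical node
#' set of a finite-element head model: an outer cortical shell and an inner
#' shell whose nodes carry the sublobar label. Nodes are placed on a Fibonacci
#' lattice over a spherical cap reaching 40 degrees below the equator (so
#' lateral-inferior temporal and posterior-inferior occipital territory
#' exists) with a small seeded tangential jitter, then labelled by the fixed
#' angular partition. Deterministic for a given seed.
#'
#' @param nNodes total number of nodes (outer + inner shell), at least 100.
#' @param seed integer RNG seed for the jitter.
#' @param headRadius scalp sphere radius, mm. The cortical shell sits at
#'   `0.82 * headRadius` and the inner shell at `0.35 * headRadius`.
#' @param sublobarFraction fraction of nodes placed on the inner shell.
#' @param jitterSd standard deviation (mm) of the tangential jitter.
#' @return A list with elements `cloud` ([NodeCloud-class], space
#'   `"talairach"`) and `labels` ([AtlasLabelTable-class]).
#' @examples
#' head <- buildHeadModel(2000, seed = 1)
#' table(labelTable(head$labels)$lobe)
#' @export
buildHeadModel <- function(nNodes, seed = 1L, headRadius = 85,
                           sublobarFraction = 0.12, jitterSd = 1.5) {
  if (!is.finite(nNodes) || nNodes < 100)
    stop("nNodes must be at least 100")
  nNodes <- as.integer(nNodes)
  cortexRadius <- 0.82 * headRadius
  innerRadius <- 0.35 * headRadius
  nInner <- max(1L, as.integer(round(nNodes * sublobarFraction)))
  nOuter <- nNodes - nInner
  outer <- .capLattice(nOuter, cortexRadius)
  inner <- .capLattice(nInner, innerRadius)
  coords <- rbind(outer, inner)
  coords <- .withSeed(seed, {
    jit <- matrix(stats::rnorm(3L * nNodes, sd = jitterSd), ncol = 3)
    shell <- rep(c(cortexRadius, innerRadius), c(nOuter, nInner))
    jittered <- coords + jit
    .unitRows(jittered) * shell          # re-project jitter onto the shell
  })
  colnames(coords) <- c("x", "y", "z")
  cloud <- NodeCloud(seq_len(nNodes), coords, space = "talairach")
  labels <- syntheticAtlasLabels(cloud, cortexRadius, innerRadius)
  list(cloud = cloud, labels = labels)
}

# Evaluate expr with a temporary RNG seed, restoring global RNG state after.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
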