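# Phenomenological field generator. Not a finite-element solve: the analysis
# pipeline consumes per-node scalars only, and the generator reproduces the
# qualitative structure such fields share -- a peak on the cortex near the
# anode, spread of current toward the cathode along the anode-cathode path,
# strict linearity in the total current, and sharper/hotter fields for
# smaller electrodes.

.REFERENCE_AREA <- 25  # cm^2, the 5 x 5 electrode

# great-circle arc between two scalp sites, sampled about every 2 degrees,
# projected radially onto the cortical shell radius
.arcSamples <- function(a, b, radius, stepDeg = 2) {
  ua <- .unit(a); ub <- .unit(b)
  ang <- acos(max(-1, min(1, sum(ua * ub))))
  nseg <- max(2L, ceiling(ang / (stepDeg * pi / 180)))
  t(vapply(seq(0, 1, length.out = nseg + 1L),
           function(t) .slerp(ua, ub, t) * radius, numeric(3)))
}

# minimum Euclidean distance from each row of coords to any row of pts
.minDistToPoints <- function(coords, pts) {
  d2 <- rep(Inf, nrow(coords))
  for (k in seq_len(nrow(pts))) {
    dk <- (coords[, 1] - pts[k, 1])^2 + (coords[, 2] - pts[k, 2])^2 +
      (coords[, 3] - pts[k, 3])^2
    d2 <- pmin(d2, dk)
  }
  sqrt(d2)
}

#' Simulate a per-node scalar field for one montage
#'
#' Generates an MCD-like field on a node cloud: a Gaussian source centred on
#' the cortical projection of the anode plus a weighted Gaussian leak along
#' the anode-to-cathode great-circle path (sampled on the scalp and projected
#' radially to the cortical shell), with additive seeded noise clipped at
#' zero. Per node,
#'
#' `value = (current / 2) * gain * (G(d_anode; sigma) + leak * G(d_path; pathSigma)) + noise`
#'
#' where `gain = (25 / area)^peakGainExponent` and
#' `sigma = sigma0 * (area / 25)^sizeSpreadExponent` implement the
#' electrode-size laws (smaller electrodes: higher peak, tighter spread), and
#' `G` is an unnormalised Gaussian kernel over Euclidean distance. The field
#' is strictly linear in `current` when `noiseSd = 0`, and deterministic given
#' the seed.
#'
#' @param montage a [MontageSpec-class]; anode and cathode must exist in
#'   `layout`.
#' @param cloud a [NodeCloud-class] sharing the head frame of `layout`.
#' @param layout an [ElectrodeLayout-class].
#' @param params a [SimulationParams-class].
#' @param seed RNG seed for the noise draw; defaults to the seed stored in
#'   `params`. Unused when `noiseSd = 0`.
#' @return A [FieldVector-class] of kind `"MCD"` named after the montage.
#' @examples
#' head <- buildHeadModel(1000, seed = 1)
#' layout <- layoutElectrodes(85)
#' f <- simulateField(parseMontageName("CP5_CZ_5_5"), head$cloud, layout,
#'                    SimulationParams())
#' max(fieldValues(f))
#' @export
simulateField <- function(montage, cloud, layout, params = SimulationParams(),
                          seed = NULL) {
  stopifnot(is(montage, "MontageSpec"), is(cloud, "NodeCloud"),
            is(layout, "ElectrodeLayout"), is(params, "SimulationParams"))
  anode <- sitePosition(layout, montage@anode)
  cathode <- sitePosition(layout, montage@cathode)
  coords <- nodeCoords(cloud)
  # cortical shell radius: the typical node radius of the cloud
  rc <- stats::median(sqrt(rowSums(coords^2)))

  area <- montage@sizeL * montage@sizeB
  sigma <- params@sigma0 * (area / .REFERENCE_AREA)^params@sizeSpreadExponent
  gain <- (.REFERENCE_AREA / area)^params@peakGainExponent

  src <- .unit(anode) * rc
  dAnode <- sqrt((coords[, 1] - src[1])^2 + (coords[, 2] - src[2])^2 +
                 (coords[, 3] - src[3])^2)
  base <- exp(-dAnode^2 / (2 * sigma^2))
  if (params@leakFraction > 0) {
    arc <- .arcSamples(anode, cathode, rc)
    dPath <- .minDistToPoints(coords, arc)
    base <- base + params@leakFraction * exp(-dPath^2 / (2 * params@pathSigma^2))
  }
  values <- (montage@current / 2) * gain * base
  if (params@noiseSd > 0) {
    if (is.null(seed)) seed <- params@seed
    noise <- .withSeed(seed, stats::rnorm(nrow(coords), sd = params@noiseSd))
    values <- pmax(0, values + noise)
  }
  FieldVector(nodeIds(cloud), values, kind = "MCD",
              montageName = formatMontageName(montage))
}
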