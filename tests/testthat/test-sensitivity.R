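# Electrode displacement and current-intensity sensitivity.

test_that("electrode perturbation yields four on-sphere points at 10 mm geodesic", {
  layout <- layoutElectrodes(85)
  for (site in c("CP5", "TP7", "neck_nape")) {
    p <- sitePosition(layout, site)
    disp <- perturbElectrode(p, 85, 10)
    expect_identical(rownames(disp),
                     c("superior", "inferior", "anterior", "posterior"))
    for (k in 1:4) {
      q <- disp[k, ]
      expect_lt(abs(sqrt(sum(q^2)) - 85), 1e-6)          # stays on the sphere
      geo <- 85 * acos(sum(p * q) / (85 * 85))
      expect_lt(abs(geo - 10), 0.01)
    }
  }
  # vertex: tangent frame degenerates, fixed fallback still gives 4 points
  dispCZ <- perturbElectrode(c(0, 0, 85), 85, 10)
  expect_identical(nrow(unique(round(dispCZ, 9))), 4L)
  geo <- apply(dispCZ, 1, function(q) 85 * acos(sum(c(0, 0, 85) * q) / 85^2))
  expect_true(all(abs(geo - 10) < 0.01))
})

test_that("intensity halving is exact with noise off and leaves scale-free statistics unchanged", {
  exp <- standardExperiment()
  res <- intensitySensitivity(parseMontageName("CP5_CZ_5_5"), exp$head$cloud,
                              exp$head$labels, exp$layout, exp$params)
  expect_equal(unname(res$ratios), rep(0.5, length(res$ratios)),
               tolerance = 1e-12)
  expect_true(res$thresholdSetsIdentical)
  expect_false(res$maxLobeChanged)

  # the pair statistic r is unchanged by a global intensity change
  lowParams <- exp$params
  mk <- function(name, current) {
    simulateField(parseMontageName(name, current = current), exp$head$cloud,
                  exp$layout, lowParams)
  }
  rAt <- function(current) {
    a <- thresholdField(mk("CP5_CZ_5_5", current), labels = exp$head$labels)
    b <- thresholdField(mk("TP7_Neck_5_5", current), labels = exp$head$labels)
    c <- thresholdField(mk("TP7_CZ_5_5", current), labels = exp$head$labels)
    p1 <- overlapProportion(countOverlap(a, c), nAbove(a))
    p2 <- overlapProportion(countOverlap(a, b), nAbove(a))
    pairRatio(p1, p2)$r
  }
  expect_equal(rAt(2), rAt(1), tolerance = 1e-12)
})

test_that("with noise, replicated runs detect the decrease at 1 mA", {
  h <- buildHeadModel(1500, seed = 4)
  layout <- layoutElectrodes(85)
  noisy <- SimulationParams(noiseSd = 0.02)
  res <- intensitySensitivity(parseMontageName("TP7_Neck_5_5"), h$cloud,
                              h$labels, layout, noisy, seeds = 1:20)
  expect_gt(res$pairedTest$tStat, 0)
  expect_lt(res$pairedTest$pValue, 0.01)
  expect_identical(res$pairedTest$direction, "decrease at lower current")
})

test_that("1 cm displacements leave the selectivity configuration unchanged at defaults", {
  exp <- standardExperiment()
  for (nm in c("CP5_CZ_5_5", "TP7_Neck_5_5")) {
    res <- displacementSensitivity(parseMontageName(nm), exp$head$cloud,
                                   exp$head$labels, exp$layout, exp$params)
    expect_length(res$variants, 8L)
    expect_false(res$anyMaxLobeChanged)
    expect_true(all(is.finite(unlist(lapply(res$variants, `[[`, "deltas")))))
  }
})

test_that("a zero-length displacement reproduces the baseline exactly", {
  h <- buildHeadModel(1200, seed = 9)
  layout <- layoutElectrodes(85)
  res <- displacementSensitivity(parseMontageName("CP5_CZ_5_5"), h$cloud,
                                 h$labels, layout, SimulationParams(),
                                 distanceMm = 0)
  for (v in res$variants) {
    expect_false(v$maxLobeChanged)
    expect_true(all(abs(v$deltas) == 0))
  }
})

test_that("a sharp source on a lobe boundary flips the maximum under displacement", {
  h <- buildHeadModel(4000, seed = 2)
  layout <- layoutElectrodes(85)
  # synthetic site exactly on the parietal/temporal boundary (12 deg
  # elevation) on the left lateral surface
  u <- c(sin(78 * pi / 180) * cos(200 * pi / 180),
         sin(78 * pi / 180) * sin(200 * pi / 180),
         cos(78 * pi / 180))
  pos <- rbind(layout@positions, X1 = 85 * u)
  boundaryLayout <- new("ElectrodeLayout", positions = pos, headRadius = 85)
  sharp <- SimulationParams(sigma0 = 5, leakFraction = 0)
  res <- displacementSensitivity(MontageSpec("X1", "CZ"), h$cloud, h$labels,
                                 boundaryLayout, sharp)
  expect_true(res$anyMaxLobeChanged)
})
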