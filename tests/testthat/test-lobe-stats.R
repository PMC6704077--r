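# Lobe selectivity configuration: per-category statistics, exceedance, ANOVA
# and the electrode-size comparison.

test_that("a constant field gives equal means, empty exceedance, zero spread", {
  cloud <- randomCloud(600, seed = 1)
  labels <- randomLabels(cloud, seed = 2)
  f <- FieldVector(nodeIds(cloud), rep(0.4, 600), montageName = "const")
  s <- lobeStatistics(f, labels)
  expect_true(all(abs(perLobeTable(s)$mean - 0.4) < 1e-15))
  expect_equal(avgAcrossLobes(s), 0.4)
  expect_length(exceedanceProfile(s), 0)
  expect_identical(spreadCount(s), 0L)
})

test_that("a field supported on one category names it max_MCD", {
  cloud <- randomCloud(600, seed = 3)
  labels <- randomLabels(cloud, seed = 4)
  lt <- labelTable(labels)
  vals <- ifelse(lt$hemisphere == "left" & lt$lobe == "parietal", 1, 0)
  s <- lobeStatistics(FieldVector(lt$node_id, vals, montageName = "lp"), labels)
  expect_identical(maxLobe(s), c("left", "parietal"))
})

test_that("lobe statistics agree exactly with an independent grouping oracle", {
  for (seed in 1:5) {
    cloud <- randomCloud(500, seed = seed)
    labels <- randomLabels(cloud, seed = seed + 100)
    field <- randomField(cloud, seed = seed + 200)
    s <- lobeStatistics(field, labels)
    oracle <- oracleLobeStats(field, labels)
    tab <- perLobeTable(s)
    keys <- paste(tab$hemisphere, tab$lobe)
    expect_setequal(keys, names(oracle))
    for (i in seq_along(keys)) {
      o <- oracle[[keys[i]]]
      expect_equal(tab$n[i], unname(o["n"]))
      expect_equal(tab$mean[i], unname(o["mean"]), tolerance = 1e-12)
      expect_equal(tab$sd[i], unname(o["sd"]), tolerance = 1e-12)
    }
    oMeans <- vapply(oracle, `[[`, numeric(1), "mean")
    expect_equal(avgAcrossLobes(s), mean(oMeans), tolerance = 1e-12)
    expect_identical(paste(maxLobe(s), collapse = " "),
                     names(oMeans)[which.max(oMeans)])
    # avg lies between the extreme category means
    expect_gte(avgAcrossLobes(s), min(oMeans))
    expect_lte(avgAcrossLobes(s), max(oMeans))
  }
})

test_that("exceedance follows its defining formula", {
  expect_equal(exceedancePercent(0.30, 0.15), 100)
  expect_equal(exceedancePercent(0.2, 0.2), 0)
  expect_equal(exceedancePercent(0.218, 0.10), 118)
  expect_error(exceedancePercent(0.1, 0), "positive")
  expect_error(exceedancePercent(0.1, -1), "positive")
})

test_that("global positive scaling preserves the selectivity configuration", {
  cloud <- randomCloud(800, seed = 7)
  labels <- randomLabels(cloud, seed = 8)
  field <- randomField(cloud, seed = 9)
  s1 <- lobeStatistics(field, labels)
  k <- 3.7
  s2 <- lobeStatistics(FieldVector(nodeIds(field), k * field@values,
                                   montageName = "scaled"), labels)
  expect_equal(perLobeTable(s2)$mean, k * perLobeTable(s1)$mean)
  expect_equal(perLobeTable(s2)$sd, k * perLobeTable(s1)$sd)
  expect_equal(avgAcrossLobes(s2), k * avgAcrossLobes(s1))
  expect_identical(maxLobe(s2), maxLobe(s1))
  expect_equal(exceedanceProfile(s2), exceedanceProfile(s1))
  expect_identical(spreadCount(s2), spreadCount(s1))
})

test_that("one-way ANOVA matches a hand-computed instance and handles degeneracies", {
  # 9-value, 3-group instance with the F statistic computed from first
  # principles in this test
  vals <- c(1, 2, 3, 2, 4, 6, 8, 9, 10)
  grp <- rep(c("a", "b", "c"), each = 3)
  grand <- mean(vals)
  ssb <- sum(3 * (tapply(vals, grp, mean) - grand)^2)
  ssw <- sum((vals - rep(tapply(vals, grp, mean), each = 3))^2)
  fExpected <- (ssb / 2) / (ssw / 6)

  cloud <- NodeCloud(1:9, matrix(as.numeric(1:27), 9, 3))
  labels <- AtlasLabelTable(1:9, rep("left", 9),
                            rep(c("frontal", "parietal", "temporal"), each = 3),
                            rep("G", 9))
  res <- anovaAcrossLobes(FieldVector(1:9, vals, montageName = "toy"), labels)
  expect_equal(res$fStat, fExpected, tolerance = 1e-9)
  expect_identical(res$dfBetween, 2L)
  expect_identical(res$dfWithin, 6L)
  expect_equal(res$pValue, pf(fExpected, 2, 6, lower.tail = FALSE))
  expect_identical(nrow(res$tukey), 3L)

  # equal constant groups -> F = 0
  flat <- anovaAcrossLobes(FieldVector(1:9, rep(2, 9), montageName = "flat"),
                           labels)
  expect_identical(flat$fStat, 0)

  # separated constant groups -> p < 0.001
  labels2 <- AtlasLabelTable(1:6, rep("left", 6),
                             rep(c("frontal", "parietal"), each = 3), rep("G", 6))
  sep <- anovaAcrossLobes(FieldVector(1:6, c(0, 0, 0, 1, 1, 1),
                                      montageName = "sep"), labels2)
  expect_lt(sep$pValue, 0.001)

  one <- AtlasLabelTable(1:4, rep("left", 4), rep("frontal", 4), rep("G", 4))
  expect_error(anovaAcrossLobes(FieldVector(1:4, 1:4 / 4, montageName = "x"),
                                one), "at least two")
})

test_that("electrode-size comparison detects the 3x3 intensity gain", {
  h <- buildHeadModel(3000, seed = 2)
  layout <- layoutElectrodes(85)
  params <- SimulationParams()
  f55 <- simulateField(parseMontageName("CP5_CZ_5_5"), h$cloud, layout, params)
  f33 <- simulateField(parseMontageName("CP5_CZ_3_3"), h$cloud, layout, params)
  cmp <- compareSizes(list(f55, f33), h$labels,
                      targetLobe = c("left", "parietal"))
  expect_gt(cmp$targetMeans[["CP5_CZ_3_3"]], cmp$targetMeans[["CP5_CZ_5_5"]])
  expect_false(cmp$selectivityChanged)

  # identical fields across "sizes" -> no selectivity change, F ~ 0
  same <- compareSizes(list(a = f55, b = f55), h$labels)
  expect_false(same$selectivityChanged)
  expect_lt(same$anova$fStat, 1e-20)

  expect_error(compareSizes(list(f55), h$labels), "at least two")
  expect_error(compareSizes(list(a = f55, b = f33), h$labels,
                            targetLobe = c("left", "nonsense")),
               "no labelled nodes")
})
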