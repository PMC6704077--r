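# The three-principle selection procedure.

mkStats <- function(montage, maxHemi, maxLobe, spread, exceed) {
  # minimal LobeStats stand-in built through the public constructor path
  perLobe <- data.frame(hemisphere = c(maxHemi, "left"),
                        lobe = c(maxLobe, "limbic"),
                        n = c(10L, 10L), mean = c(1, 0.1), sd = c(0.1, 0.1))
  new("LobeStats", perLobe = perLobe, maxLobe = c(maxHemi, maxLobe),
      maxValue = 1, avgAcrossLobes = 0.5, exceedance = exceed,
      spreadCount = as.integer(spread), montageName = montage)
}

test_that("principle 1 keeps target-lobe montages and ranks by spread", {
  off <- mkStats("M1", "left", "temporal", 0, c(`left temporal` = 50))
  res <- principle1Screen(list(M1 = off), c("left", "parietal"))
  expect_length(res$survivors, 0)

  a <- mkStats("A", "left", "parietal", 1,
               c(`left parietal` = 80, `left frontal` = 10))
  b <- mkStats("B", "left", "parietal", 3,
               c(`left parietal` = 70, `left frontal` = 30))
  res <- principle1Screen(list(A = a, B = b), c("left", "parietal"))
  expect_identical(res$survivors, c("A", "B"))

  # shared maximum with another lobe excludes the montage
  sharedTab <- data.frame(hemisphere = c("left", "left"),
                          lobe = c("parietal", "temporal"),
                          n = c(5L, 5L), mean = c(1, 1 - 1e-9), sd = c(0, 0))
  shared <- new("LobeStats", perLobe = sharedTab,
                maxLobe = c("left", "parietal"), maxValue = 1,
                avgAcrossLobes = 0.9, exceedance = c(`left parietal` = 11),
                spreadCount = 0L, montageName = "S")
  res <- principle1Screen(list(S = shared, A = a), c("left", "parietal"))
  expect_identical(res$survivors, "A")
  expect_true(res$table$sharedMax[res$table$montage == "S"])
})

test_that("principle 2 picks the minimal-overlap pair deterministically", {
  tab <- data.frame(dorsal = "CP5_CZ_5_5",
                    ventral = c("TP7_CZ_5_5", "TP7_SO_5_5", "TP7_Maxilla_5_5",
                                "TP7_TP8_5_5", "TP7_Neck_5_5"),
                    nAboveDorsal = 1695L, nAboveVentral = 1000L,
                    nOverlap = c(903L, 298L, 405L, 205L, 57L),
                    p = c(903, 298, 405, 205, 57) / 1695)
  best <- principle2BestPair(tab)
  expect_identical(best$winner, c("CP5_CZ_5_5", "TP7_Neck_5_5"))
  expect_identical(best$nOverlap, 57L)
  expect_false(best$tied)

  tied <- tab; tied$nOverlap <- 100L
  bestTied <- principle2BestPair(tied)
  expect_true(bestTied$tied)
  expect_identical(bestTied$winner[2], "TP7_CZ_5_5")  # lexicographic

  set.seed(71)   # brute-force argmin scan on a random matrix
  rnd <- data.frame(dorsal = rep(c("D1", "D2", "D3"), each = 3),
                    ventral = rep(c("V1", "V2", "V3"), 3),
                    nAboveDorsal = 100L, nAboveVentral = 100L,
                    nOverlap = sample(1:1000, 9))
  rnd$p <- rnd$nOverlap / 100
  best <- principle2BestPair(rnd)
  iMin <- which.min(rnd$nOverlap)
  expect_identical(best$winner, c(rnd$dorsal[iMin], rnd$ventral[iMin]))
  expect_error(principle2BestPair(rnd[0, ]), "empty")
})

test_that("principle 3 verifies target gyri among the top clusters", {
  cl <- data.frame(hemisphere = "left",
                   gyrus = c("Supramarginal Gyrus", "Angular Gyrus", "X"),
                   nNodes = 1:3, cmcd = c(3, 2, 1), rank = 1:3)
  hit <- principle3Verify(cl, "Supramarginal Gyrus", topK = 5)
  expect_true(hit$verified)
  expect_identical(hit$found$rank, 1L)
  miss <- principle3Verify(cl, "Lingual Gyrus", topK = 5)
  expect_false(miss$verified)
  # topK truncation matters
  deep <- principle3Verify(cl, "X", topK = 2)
  expect_false(deep$verified)
})

test_that("the full synthetic experiment selects the expected montage pair", {
  exp <- standardExperiment()
  report <- selectMontages(exp$dorsal, exp$ventral, exp$head$labels)
  expect_identical(finalPair(report), c("CP5_CZ_5_5", "TP7_Neck_5_5"))
  expect_identical(report@principle1$survivors$dorsal[1], "CP5_CZ_5_5")
  expect_identical(report@principle1$survivors$ventral[1], "TP7_Neck_5_5")
  expect_true(report@principle3$dorsal$verified)
  expect_true(report@principle3$ventral$verified)

  # pure function of its inputs
  report2 <- selectMontages(exp$dorsal, exp$ventral, exp$head$labels)
  expect_identical(finalPair(report2), finalPair(report))
  expect_identical(report2@principle2$pairs, report@principle2$pairs)

  # removing a non-winning montage does not change the outcome
  fewer <- selectMontages(exp$dorsal[names(exp$dorsal) != "CP5_SO_5_5"],
                          exp$ventral[names(exp$ventral) != "TP7_CZ_5_5"],
                          exp$head$labels)
  expect_identical(finalPair(fewer), finalPair(report))
})

test_that("a single qualifying dorsal/ventral pair is selected directly", {
  exp <- standardExperiment()
  report <- selectMontages(exp$dorsal["CP5_CZ_5_5"],
                           exp$ventral["TP7_Neck_5_5"], exp$head$labels)
  expect_identical(finalPair(report), c("CP5_CZ_5_5", "TP7_Neck_5_5"))
  expect_identical(nrow(report@principle2$pairs), 1L)
})

test_that("an impossible cluster target yields no final pair with a reason", {
  exp <- standardExperiment()
  targets <- selectionTargets(dorsalGyri = "No Such Gyrus")
  report <- selectMontages(exp$dorsal, exp$ventral, exp$head$labels,
                           targets = targets)
  expect_identical(finalPair(report), "none")
  expect_match(report@principle3$failureReason, "verification failed")
})
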