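# Fraction-of-max thresholding, overlap counts and the p / r statistics.

test_that("threshold is the stated fraction of the maximum", {
  f <- FieldVector(1:4, c(0.03, 0.02, 0.0151, 0.001), montageName = "toy")
  ts <- thresholdField(f, 0.5)
  expect_equal(thresholdValue(ts), 0.015)
  expect_setequal(aboveThresholdIds(ts), c(1L, 2L, 3L))
  expect_identical(nAbove(ts), 3L)

  # ties at exactly the threshold are excluded; the max always passes
  f2 <- FieldVector(1:3, c(0.03, 0.015, 0.001), montageName = "tie")
  expect_setequal(aboveThresholdIds(thresholdField(f2, 0.5)), 1L)

  const <- FieldVector(1:5, rep(2, 5), montageName = "const")
  expect_identical(nAbove(thresholdField(const, 0.5)), 5L)

  expect_error(thresholdField(FieldVector(1:3, rep(0, 3), montageName = "z")),
               "all-zero")
  expect_error(thresholdField(f, 0), "strictly between")
  expect_error(thresholdField(f, 1), "strictly between")
})

test_that("thresholding matches a brute-force filter and is monotone in the fraction", {
  cloud <- randomCloud(200, seed = 41)
  f <- randomField(cloud, seed = 42)
  ts <- thresholdField(f, 0.5)
  vals <- fieldValues(f)
  keep <- integer(0)                      # explicit scan
  thr <- 0.5 * max(vals)
  for (i in seq_along(vals)) if (vals[[i]] > thr) keep <- c(keep, nodeIds(f)[i])
  expect_setequal(aboveThresholdIds(ts), keep)

  prev <- Inf
  for (fr in c(0.2, 0.4, 0.6, 0.8)) {
    n <- nAbove(thresholdField(f, fr))
    expect_lte(n, prev)
    prev <- n
  }
})

test_that("thresholding can restrict its support to labelled nodes", {
  cloud <- randomCloud(100, seed = 43)
  f <- randomField(cloud, seed = 44)
  labels <- randomLabels(cloud, seed = 45)
  half <- AtlasLabelTable(nodeIds(cloud)[1:50], labels@hemisphere[1:50],
                          labels@lobe[1:50], labels@gyrus[1:50])
  ts <- thresholdField(f, 0.5, labels = half)
  expect_true(all(aboveThresholdIds(ts) %in% nodeIds(cloud)[1:50]))
  expect_equal(thresholdValue(ts), 0.5 * max(fieldValues(f)[1:50]))
})

mkSet <- function(ids, name = "s") {
  new("ThresholdedSet", montageName = name, fraction = 0.5, threshold = 1,
      nodeId = as.integer(ids), nAbove = length(ids))
}

test_that("overlap counting is an exact, symmetric intersection", {
  a <- mkSet(1:10)
  expect_identical(countOverlap(a, a), 10L)
  expect_identical(countOverlap(mkSet(1:5), mkSet(6:9)), 0L)

  set.seed(46)
  x <- mkSet(sample(1:2000, 300))
  y <- mkSet(sample(1:2000, 300))
  hits <- 0L                                # quadratic scan oracle
  for (i in x@nodeId) for (j in y@nodeId) if (i == j) hits <- hits + 1L
  expect_identical(countOverlap(x, y), hits)
  expect_identical(countOverlap(x, y), countOverlap(y, x))
})

test_that("overlap proportion reproduces the published worked counts", {
  expect_equal(round(overlapProportion(903, 1695), 2), 0.53)
  expect_equal(overlapProportion(7, 7), 1)
  expect_message(p0 <- overlapProportion(0, 100), "boundary")
  expect_equal(p0, 0)
  expect_error(overlapProportion(1, 0), "positive")
  expect_error(overlapProportion(10, 5), "exceed")
})

test_that("the contrast ratio r reproduces the published table values", {
  expect_equal(round(pairRatio(903 / 1695, 213 / 1092)$r, 2), 0.46)
  expect_equal(round(pairRatio(903 / 1695, 679 / 1465)$r, 2), 0.07)
  expect_equal(round(pairRatio(903 / 1695, 57 / 1397)$r, 2), 0.86)

  expect_equal(pairRatio(0.3, 0.3)$r, 0)
  expect_equal(pairRatio(0.2, 0.5)$r, pairRatio(0.5, 0.2)$r)
  set.seed(47)
  for (i in 1:20) {
    p <- runif(2)
    r <- pairRatio(p[1], p[2])$r
    expect_gte(r, 0); expect_lte(r, 1)
  }
  expect_gt(pairRatio(1, 1e-9)$r, 0.99)     # r -> 1 as one p vanishes
  expect_error(pairRatio(0, 0), "undefined")
  expect_error(pairRatio(-0.1, 0.5), "non-negative")
})

test_that("the all-pairs table is consistent with pairwise recomputation", {
  set.seed(48)
  dorsal <- lapply(1:3, function(i) mkSet(sample(1:500, 80), paste0("D", i)))
  ventral <- lapply(1:3, function(i) mkSet(sample(1:500, 60), paste0("V", i)))
  tab <- allPairsOverlap(dorsal, ventral)
  expect_identical(nrow(tab), 9L)
  for (k in seq_len(nrow(tab))) {
    a <- dorsal[[match(tab$dorsal[k], paste0("D", 1:3))]]
    b <- ventral[[match(tab$ventral[k], paste0("V", 1:3))]]
    expect_identical(tab$nOverlap[k], countOverlap(a, b))
    expect_equal(tab$p[k], overlapProportion(countOverlap(a, b), nAbove(a)))
  }
  one <- allPairsOverlap(list(mkSet(1:5)), list(mkSet(1:5)))
  expect_identical(nrow(one), 1L)
  expect_equal(one$p, 1)
  expect_error(allPairsOverlap(list(), ventral), "non-empty")
})

test_that("threshold sets and overlap statistics are scale invariant", {
  cloud <- randomCloud(400, seed = 49)
  fa <- randomField(cloud, seed = 50, montageName = "A")
  fb <- randomField(cloud, seed = 51, montageName = "B")
  k <- 12.5
  scale <- function(f) FieldVector(nodeIds(f), k * f@values,
                                   montageName = montageName(f))
  ta <- thresholdField(fa); tb <- thresholdField(fb)
  sa <- thresholdField(scale(fa)); sb <- thresholdField(scale(fb))
  expect_setequal(aboveThresholdIds(ta), aboveThresholdIds(sa))
  expect_identical(countOverlap(ta, tb), countOverlap(sa, sb))
  p1 <- overlapProportion(countOverlap(ta, tb), nAbove(ta))
  p1s <- overlapProportion(countOverlap(sa, sb), nAbove(sa))
  expect_equal(p1, p1s)
})
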