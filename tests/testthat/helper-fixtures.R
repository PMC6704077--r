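# Shared fixtures. Everything is generated in code; the standard synthetic
# experiment (10k-node head, ten 5 x 5 montages, noise off) is built once per
# test run and cached.

.fixtures <- new.env(parent = emptyenv())

# a random cloud scattered over the two shells of the standard head geometry
randomCloud <- function(n, seed, space = "talairach") {
  set.seed(seed)
  u <- matrix(rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  r <- sample(c(0.82 * 85, 0.35 * 85), n, replace = TRUE)
  NodeCloud(seq_len(n), u * r, space = space)
}

# arbitrary labels over the full 12-category scheme
randomLabels <- function(cloud, seed, gyri = paste("Gyrus", LETTERS[1:8])) {
  set.seed(seed)
  n <- length(nodeIds(cloud))
  AtlasLabelTable(nodeIds(cloud),
                  sample(c("left", "right"), n, replace = TRUE),
                  sample(c("frontal", "parietal", "temporal", "occipital",
                           "limbic", "sublobar"), n, replace = TRUE),
                  sample(gyri, n, replace = TRUE))
}

randomField <- function(cloud, seed, montageName = "random") {
  set.seed(seed)
  FieldVector(nodeIds(cloud), runif(length(nodeIds(cloud))),
              montageName = montageName)
}

# the standard synthetic experiment used by the end-to-end tests
standardExperiment <- function() {
  if (is.null(.fixtures$exp)) {
    head <- buildHeadModel(10000, seed = 1)
    layout <- layoutElectrodes(85)
    params <- SimulationParams()
    fields <- lapply(enumerateStandardMontages(5, 5), simulateField,
                     cloud = head$cloud, layout = layout, params = params)
    .fixtures$exp <- list(head = head, layout = layout, params = params,
                          fields = fields,
                          dorsal = fields[grepl("^CP5_", names(fields))],
                          ventral = fields[grepl("^TP7_", names(fields))])
  }
  .fixtures$exp
}

# independent per-node re-implementation of the head-model partition rules
# (scalar logic, written separately from the vectorised implementation)
oraclePartition <- function(coord, cortexRadius = 0.82 * 85,
                            innerRadius = 0.35 * 85) {
  r <- sqrt(sum(coord^2))
  u <- coord / r
  e <- asin(max(-1, min(1, u[3]))) * 180 / pi
  l <- abs(u[1])
  hemisphere <- if (u[1] <= 0) "left" else "right"
  if (r < (cortexRadius + innerRadius) / 2) {
    lobe <- "sublobar"
  } else if (l < 0.15 && e < 55) {
    lobe <- "limbic"
  } else if (e >= 12) {
    lobe <- if (u[2] > 0.25) "frontal" else "parietal"
  } else if (u[2] < -0.72) {
    lobe <- "occipital"
  } else if (l >= 0.35 && u[2] < 0.25) {
    lobe <- "temporal"
  } else if (u[2] > 0) {
    lobe <- "frontal"
  } else {
    lobe <- "occipital"
  }
  c(hemisphere = hemisphere, lobe = lobe)
}

# independent grouped mean/sd oracle for lobe statistics
oracleLobeStats <- function(field, labels) {
  lt <- labelTable(labels)
  vals <- fieldValues(field)
  out <- list()
  for (h in unique(lt$hemisphere)) for (lo in unique(lt$lobe)) {
    ids <- lt$node_id[lt$hemisphere == h & lt$lobe == lo]
    if (length(ids) == 0) next
    v <- vals[as.character(ids)]
    out[[paste(h, lo)]] <- c(n = length(v), mean = mean(v), sd = sd(v))
  }
  out
}
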