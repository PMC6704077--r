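# Lobe selectivity configuration analysis: per-(hemisphere, lobe) field
# statistics, the max_MCD / avg_MCD profile, and the node-level ANOVA used to
# compare lobes and electrode sizes.

.categoryKey <- function(hemisphere, lobe) paste(hemisphere, lobe)

# join field values with labels; returns data.frame(value, hemisphere, lobe,
# gyrus) over the common node set
.joinFieldLabels <- function(field, labels) {
  stopifnot(is(field, "FieldVector"), is(labels, "AtlasLabelTable"))
  idx <- match(labels@nodeId, field@nodeId)
  keep <- !is.na(idx)
  if (!any(keep)) stop("field and labels share no nodes")
  data.frame(node_id = labels@nodeId[keep],
             value = field@values[idx[keep]],
             hemisphere = labels@hemisphere[keep],
             lobe = labels@lobe[keep],
             gyrus = labels@gyrus[keep],
             stringsAsFactors = FALSE)
}

#' Per-lobe field statistics (lobe selectivity configuration)
#'
#' Computes, for one montage's field, the mean and standard deviation of the
#' field over each (hemisphere, lobe) category, the category with maximum mean
#' (max_MCD), the unweighted mean of the category means (avg_MCD), the percent
#' exceedance of every above-average category and the spread count (number of
#' non-maximum categories above avg_MCD). Categories with no labelled node are
#' omitted rather than treated as zero.
#'
#' @param field a [FieldVector-class].
#' @param labels an [AtlasLabelTable-class] covering the field's node set.
#' @return A [LobeStats-class].
#' @examples
#' head <- buildHeadModel(2000, seed = 1)
#' f <- simulateField(parseMontageName("CP5_CZ_5_5"), head$cloud,
#'                    layoutElectrodes(85), SimulationParams())
#' lobeStatistics(f, head$labels)
#' @export
lobeStatistics <- function(field, labels) {
  df <- .joinFieldLabels(field, labels)
  key <- .categoryKey(df$hemisphere, df$lobe)
  split_vals <- split(df$value, key)
  cats <- names(split_vals)
  means <- vapply(split_vals, mean, numeric(1))
  sds <- vapply(split_vals, stats::sd, numeric(1))
  ns <- vapply(split_vals, length, integer(1))
  parts <- do.call(rbind, strsplit(cats, " ", fixed = TRUE))
  perLobe <- data.frame(hemisphere = parts[, 1], lobe = parts[, 2],
                        n = ns, mean = unname(means), sd = unname(sds),
                        row.names = NULL, stringsAsFactors = FALSE)
  avg <- mean(means)
  iMax <- which.max(means)        # ties: first in alphabetical category order
  above <- means > avg
  exceed <- 100 * (means[above] - avg) / avg
  new("LobeStats", perLobe = perLobe,
      maxLobe = c(perLobe$hemisphere[iMax], perLobe$lobe[iMax]),
      maxValue = unname(means[iMax]), avgAcrossLobes = avg,
      exceedance = exceed,
      spreadCount = as.integer(sum(above) - as.integer(above[iMax])),
      montageName = field@montageName)
}

#' Percent by which a lobe mean exceeds the cross-lobe average
#'
#' `100 * (lobeMean - avg) / avg`, the exceedance margin used by the lobe
#' selectivity configuration analysis.
#'
#' @param lobeMean mean field value of one (hemisphere, lobe) category.
#' @param avg unweighted mean of category means (must be positive).
#' @return Exceedance in percent.
#' @examples
#' exceedancePercent(0.30, 0.15)  # 100
#' @export
exceedancePercent <- function(lobeMean, avg) {
  if (!is.finite(avg) || avg <= 0) stop("avg must be positive")
  100 * (lobeMean - avg) / avg
}

#' One-way ANOVA across (hemisphere, lobe) categories
#'
#' Treats node-level field values as independent observations grouped by
#' (hemisphere, lobe) and performs a one-way ANOVA with Tukey HSD post-hoc
#' comparisons. Node values are spatially autocorrelated, so the resulting
#' degrees of freedom replicate the conventional analysis of simulator output
#' rather than a spatially corrected inference; see the package vignette.
#'
#' Degenerate inputs are handled explicitly: with zero within-group variance,
#' `F = 0` when group means are equal and `F = Inf` (p = 0) when they differ.
#'
#' @param field a [FieldVector-class].
#' @param labels an [AtlasLabelTable-class]; at least two non-empty
#'   categories required.
#' @param alpha significance level for the Tukey flags.
#' @return A list of class `mscopeAnova`: `fStat`, `dfBetween`, `dfWithin`,
#'   `pValue`, and `tukey` (data.frame of pairwise comparisons with the
#'   pairwise t statistic `diff / se`, Tukey-adjusted p value and significance
#'   flag), or `tukey = NULL` in the degenerate zero-variance cases.
#' @export
anovaAcrossLobes <- function(field, labels, alpha = 0.05) {
  df <- .joinFieldLabels(field, labels)
  df$group <- factor(.categoryKey(df$hemisphere, df$lobe))
  .onewayAnova(df$value, df$group, alpha = alpha)
}

# shared one-way ANOVA core (also used by compareSizes)
.onewayAnova <- function(value, group, alpha = 0.05) {
  group <- droplevels(factor(group))
  k <- nlevels(group)
  if (k < 2L) stop("at least two non-empty groups are required")
  n <- length(value)
  grand <- mean(value)
  gm <- tapply(value, group, mean)
  gn <- tapply(value, group, length)
  ssb <- sum(gn * (gm - grand)^2)
  ssw <- sum((value - gm[group])^2)
  df1 <- k - 1L
  df2 <- n - k
  out <- list(dfBetween = df1, dfWithin = df2, alpha = alpha,
              groupMeans = gm, groupSizes = gn)
  if (ssw <= .Machine$double.eps * max(1, sum(value^2))) {
    if (ssb <= .Machine$double.eps * max(1, sum(value^2))) {
      out$fStat <- 0; out$pValue <- 1
    } else {
      out$fStat <- Inf; out$pValue <- 0
    }
    out$tukey <- NULL
    class(out) <- "mscopeAnova"
    return(out)
  }
  out$fStat <- (ssb / df1) / (ssw / df2)
  out$pValue <- stats::pf(out$fStat, df1, df2, lower.tail = FALSE)
  fit <- stats::aov(value ~ group, data = data.frame(value = value, group = group))
  tk <- stats::TukeyHSD(fit)$group
  msw <- ssw / df2
  pairs <- rownames(tk)
  ij <- strsplit(pairs, "-", fixed = TRUE)
  se <- vapply(ij, function(p) sqrt(msw * (1 / gn[[p[1]]] + 1 / gn[[p[2]]])),
               numeric(1))
  out$tukey <- data.frame(pair = pairs, diff = unname(tk[, "diff"]),
                          statistic = unname(tk[, "diff"]) / se,
                          pAdj = unname(tk[, "p adj"]),
                          significant = unname(tk[, "p adj"]) < alpha,
                          row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- "mscopeAnova"
  out
}

#' @export
print.mscopeAnova <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.3g\n",
              x$dfBetween, x$dfWithin, x$fStat, x$pValue))
  if (!is.null(x$tukey)) {
    sig <- x$tukey[x$tukey$significant, , drop = FALSE]
    cat(sprintf("  Tukey HSD: %d of %d pairs significant at alpha = %g\n",
                nrow(sig), nrow(x$tukey), x$alpha))
  }
  invisible(x)
}

#' Compare electrode sizes on a target lobe
#'
#' Given the same montage simulated at several electrode sizes, reports the
#' target-lobe mean per size, a one-way ANOVA (with Tukey HSD) across sizes on
#' the target-lobe node values, and whether the max_MCD lobe identity changes
#' across sizes (`selectivityChanged = FALSE` reproduces a "no difference in
#' lobe selectivity configuration" outcome).
#'
#' @param fieldsBySize named list of [FieldVector-class] objects, one per
#'   electrode size (at least two).
#' @param labels an [AtlasLabelTable-class].
#' @param targetLobe length-2 character `c(hemisphere, lobe)`.
#' @param alpha significance level.
#' @return A list of class `mscopeSizeComparison` with `targetMeans`,
#'   `anova`, `maxLobes` and `selectivityChanged`.
#' @export
compareSizes <- function(fieldsBySize, labels, targetLobe = c("left", "parietal"),
                         alpha = 0.05) {
  if (length(fieldsBySize) < 2L)
    stop("at least two electrode sizes are required")
  if (is.null(names(fieldsBySize)))
    names(fieldsBySize) <- vapply(fieldsBySize, montageName, character(1))
  targetKey <- .categoryKey(targetLobe[1], targetLobe[2])
  vals <- list(); stats <- list()
  for (nm in names(fieldsBySize)) {
    df <- .joinFieldLabels(fieldsBySize[[nm]], labels)
    sel <- .categoryKey(df$hemisphere, df$lobe) == targetKey
    if (!any(sel)) stop("target lobe has no labelled nodes: ", targetKey)
    vals[[nm]] <- df$value[sel]
    stats[[nm]] <- lobeStatistics(fieldsBySize[[nm]], labels)
  }
  value <- unlist(vals, use.names = FALSE)
  size <- factor(rep(names(vals), lengths(vals)), levels = names(vals))
  maxLobes <- vapply(stats, function(s) paste(maxLobe(s), collapse = " "),
                     character(1))
  out <- list(targetLobe = targetLobe,
              targetMeans = vapply(vals, mean, numeric(1)),
              anova = .onewayAnova(value, size, alpha = alpha),
              maxLobes = maxLobes,
              selectivityChanged = length(unique(maxLobes)) > 1L,
              perSizeStats = stats)
  class(out) <- "mscopeSizeComparison"
  out
}

#' @export
print.mscopeSizeComparison <- function(x, ...) {
  cat(sprintf("Electrode-size comparison on %s %s\n",
              x$targetLobe[1], x$targetLobe[2]))
  for (nm in names(x$targetMeans))
    cat(sprintf("  %s: target-lobe mean %.4g (max lobe: %s)\n",
                nm, x$targetMeans[[nm]], x$maxLobes[[nm]]))
  print(x$anova)
  cat(sprintf("  lobe selectivity configuration changed: %s\n",
              x$selectivityChanged))
  invisible(x)
}
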