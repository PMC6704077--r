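# Readers and writers for the tab-delimited exchange tables and the affine
# JSON, plus native -> atlas space mapping and node labelling.
#
# File dialect: UTF-8, tab-delimited, header row required, '.' decimal
# separator. Numeric columns are written with "%.17g" so write -> read
# round-trips are bit exact.

.readTsv <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0L) stop("empty table: ", path)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("missing required column(s) in ", path, ": ",
         paste(missing, collapse = ", "))
  df
}

.writeTsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1)) &
    !vapply(df, is.integer, logical(1))
  for (j in which(num)) df[[j]] <- sprintf("%.17g", df[[j]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

.asFiniteNumeric <- function(x, what) {
  y <- suppressWarnings(as.numeric(x))
  if (anyNA(y) || !all(is.finite(y)))
    stop("non-numeric or non-finite ", what)
  y
}

#' Read a node-coordinate table
#'
#' Reads a tab-delimited table with columns `node_id`, `x`, `y`, `z`
#' (coordinates in mm) into a [NodeCloud-class]. Row order is preserved.
#'
#' @param path path to the TSV file.
#' @param space coordinate space tag of the stored coordinates.
#' @return A [NodeCloud-class].
#' @seealso [writeNodeCloud()]
#' @export
readNodeCloud <- function(path, space = "native") {
  df <- .readTsv(path, c("node_id", "x", "y", "z"))
  ids <- suppressWarnings(as.integer(df$node_id))
  if (anyNA(ids)) stop("non-integer node_id values in ", path)
  if (anyDuplicated(ids))
    stop("duplicate node_id in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  coords <- cbind(x = .asFiniteNumeric(df$x, "x coordinate"),
                  y = .asFiniteNumeric(df$y, "y coordinate"),
                  z = .asFiniteNumeric(df$z, "z coordinate"))
  NodeCloud(ids, coords, space = space)
}

#' Write a node-coordinate table
#'
#' @param cloud a [NodeCloud-class].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeNodeCloud <- function(cloud, path) {
  stopifnot(is(cloud, "NodeCloud"))
  co <- nodeCoords(cloud)
  .writeTsv(data.frame(node_id = nodeIds(cloud), x = co[, "x"], y = co[, "y"],
                       z = co[, "z"]), path)
}

#' Read a per-node field table
#'
#' Reads a tab-delimited table with columns `node_id`, `value` and aligns it to
#' `cloud`: the file must cover exactly the cloud's node set. Values must be
#' finite and non-negative.
#'
#' @param path path to the TSV file.
#' @param cloud the [NodeCloud-class] the field belongs to.
#' @param kind `"MCD"` or `"MEF"`.
#' @param montageName montage name to attach (default: file name sans
#'   extension).
#' @return A [FieldVector-class] ordered like `cloud`.
#' @export
readFieldVector <- function(path, cloud, kind = "MCD", montageName = NULL) {
  stopifnot(is(cloud, "NodeCloud"))
  df <- .readTsv(path, c("node_id", "value"))
  ids <- suppressWarnings(as.integer(df$node_id))
  if (anyNA(ids)) stop("non-integer node_id values in ", path)
  if (anyDuplicated(ids)) stop("duplicate node_id in ", path)
  unknown <- setdiff(ids, nodeIds(cloud))
  if (length(unknown))
    stop("field refers to node_id(s) absent from the cloud: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  if (length(ids) != length(nodeIds(cloud)))
    stop("field does not cover every node of the cloud")
  vals <- suppressWarnings(as.numeric(df$value))
  if (anyNA(vals) || !all(is.finite(vals))) stop("non-finite field value in ", path)
  if (any(vals < 0)) stop("negative field value in ", path)
  ord <- match(nodeIds(cloud), ids)
  if (is.null(montageName))
    montageName <- sub("\\.[^.]*$", "", basename(path))
  FieldVector(nodeIds(cloud), vals[ord], kind = kind, montageName = montageName)
}

#' Write a per-node field table
#'
#' @param field a [FieldVector-class].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeFieldVector <- function(field, path) {
  stopifnot(is(field, "FieldVector"))
  .writeTsv(data.frame(node_id = field@nodeId, value = field@values), path)
}

#' Read a per-node atlas label table
#'
#' Reads a tab-delimited table with columns `node_id`, `hemisphere`, `lobe`,
#' `gyrus`.
#'
#' @param path path to the TSV file.
#' @return An [AtlasLabelTable-class].
#' @export
readAtlasLabels <- function(path) {
  df <- .readTsv(path, c("node_id", "hemisphere", "lobe", "gyrus"))
  ids <- suppressWarnings(as.integer(df$node_id))
  if (anyNA(ids)) stop("non-integer node_id values in ", path)
  AtlasLabelTable(ids, df$hemisphere, df$lobe, df$gyrus)
}

#' Write a per-node atlas label table
#'
#' @param labels an [AtlasLabelTable-class].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeAtlasLabels <- function(labels, path) {
  stopifnot(is(labels, "AtlasLabelTable"))
  .writeTsv(labelTable(labels), path)
}

#' Read / write an affine transform with mapping bounds
#'
#' The JSON carries the 16 affine entries row-major under `matrix` and an
#' axis-aligned bounding box under `bounds` (`lower` and `upper`, 3 mm values
#' each) used by [mapToAtlasSpace()] to drop out-of-atlas nodes.
#'
#' @param path JSON path.
#' @return For `readAffine`, a list with elements `affine`
#'   ([AffineTransform-class]) and `bounds` (list of `lower`, `upper`).
#' @export
readAffine <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$matrix) || length(obj$matrix) != 16L)
    stop("affine JSON must carry 16 row-major matrix entries")
  aff <- AffineTransform(matrix(as.numeric(obj$matrix), 4, 4, byrow = TRUE))
  bounds <- NULL
  if (!is.null(obj$bounds)) {
    bounds <- list(lower = as.numeric(obj$bounds$lower),
                   upper = as.numeric(obj$bounds$upper))
    if (length(bounds$lower) != 3L || length(bounds$upper) != 3L)
      stop("bounds must carry 3 lower and 3 upper values")
  }
  list(affine = aff, bounds = bounds)
}

#' @rdname readAffine
#' @param affine an [AffineTransform-class].
#' @param bounds list with `lower` and `upper` length-3 numeric vectors.
#' @export
writeAffine <- function(affine, bounds, path) {
  stopifnot(is(affine, "AffineTransform"))
  jsonlite::write_json(
    list(matrix = as.vector(t(affine@matrix)), bounds = bounds),
    path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Map a node cloud into atlas space
#'
#' Applies a homogeneous affine to every coordinate and drops nodes falling
#' outside the axis-aligned atlas bounding box, mirroring the reduction from a
#' simulator's full node set to the atlas-mappable subset. Node identifiers of
#' surviving nodes are unchanged.
#'
#' @param cloud a [NodeCloud-class] in native space.
#' @param affine an [AffineTransform-class] (native mm to Talairach mm).
#' @param bounds list with `lower` and `upper` length-3 numeric vectors (mm);
#'   nodes with any transformed coordinate outside `[lower, upper]` are
#'   dropped. `NULL` keeps all nodes.
#' @return A [NodeCloud-class] in `"talairach"` space.
#' @export
mapToAtlasSpace <- function(cloud, affine, bounds = NULL) {
  stopifnot(is(cloud, "NodeCloud"), is(affine, "AffineTransform"))
  if (coordSpace(cloud) != "native")
    stop("mapToAtlasSpace expects a native-space cloud")
  co <- nodeCoords(cloud)
  hom <- cbind(co, 1) %*% t(affine@matrix)
  out <- hom[, 1:3, drop = FALSE]
  colnames(out) <- c("x", "y", "z")
  keep <- rep(TRUE, nrow(out))
  if (!is.null(bounds)) {
    lo <- as.numeric(bounds$lower); hi <- as.numeric(bounds$upper)
    stopifnot(length(lo) == 3L, length(hi) == 3L)
    for (j in 1:3) keep <- keep & out[, j] >= lo[j] & out[, j] <= hi[j]
  }
  if (!any(keep)) stop("no nodes survive the atlas bounds")
  dropped <- sum(!keep)
  if (dropped > 0L)
    message(dropped, " node(s) fell outside the atlas bounds and were dropped")
  NodeCloud(nodeIds(cloud)[keep], out[keep, , drop = FALSE], space = "talairach")
}

#' Label the nodes of an atlas-space cloud
#'
#' Assigns (hemisphere, lobe, gyrus) to every node of a Talairach-space cloud,
#' either from a per-node label table (lookup by node identifier) or from the
#' synthetic angular partition of the head model (`atlas = "synthetic"`).
#' Nodes without a label are excluded from the returned table; the number of
#' exclusions is reported via `message()`.
#'
#' @param cloud a [NodeCloud-class] in `"talairach"` space.
#' @param atlas an [AtlasLabelTable-class], or the string `"synthetic"` to
#'   apply the built-in partition predicate to the coordinates.
#' @param ... passed to [syntheticAtlasLabels()] when `atlas = "synthetic"`.
#' @return An [AtlasLabelTable-class] covering the labelled subset of `cloud`.
#' @export
labelNodes <- function(cloud, atlas, ...) {
  stopifnot(is(cloud, "NodeCloud"))
  if (coordSpace(cloud) != "talairach")
    stop("labelNodes expects a talairach-space cloud")
  if (identical(atlas, "synthetic"))
    return(syntheticAtlasLabels(cloud, ...))
  stopifnot(is(atlas, "AtlasLabelTable"))
  idx <- match(nodeIds(cloud), nodeIds(atlas))
  unlabeled <- sum(is.na(idx))
  if (unlabeled > 0L)
    message(unlabeled, " node(s) had no atlas label and were excluded")
  keep <- !is.na(idx)
  if (!any(keep)) stop("no node of the cloud is covered by the atlas")
  idx <- idx[keep]
  AtlasLabelTable(nodeIds(cloud)[keep], atlas@hemisphere[idx],
                  atlas@lobe[idx], atlas@gyrus[idx])
}
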