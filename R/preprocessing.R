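# Preprocessing: raw probe intensities -> normalized log2-ratio matrix.
#
# Mirrors the classical two-color microarray path: background-based probe
# filtering, quantile normalization across samples, averaging of duplicate
# spots per gene, ratio formation against the vehicle control, and UPGMA
# display clustering.

#' Filter probes by local background
#'
#' Retains exactly the probes whose signal is at least `factor` times the
#' local background in every sample (inclusive comparison).  Order is
#' preserved.
#'
#' @param raw A `raw_intensity_table`.
#' @param factor Signal-to-background ratio threshold (default 1.4).
#' @return A filtered `raw_intensity_table`.
#' @export
filter_by_background <- function(raw, factor = 1.4) {
  stopifnot(inherits(raw, "raw_intensity_table"))
  if (factor <= 0) stop("factor must be positive", call. = FALSE)
  keep <- rowSums(raw$signal >= factor * raw$background) ==
    ncol(raw$signal)
  if (!any(keep)) {
    warning("background filter removed every probe")
  }
  raw_intensity_table(raw$probe_id[keep], raw$gene_id[keep],
                      raw$signal[keep, , drop = FALSE],
                      raw$background[keep, , drop = FALSE])
}

#' Quantile-normalize a samples-in-columns matrix
#'
#' After normalization every column has the identical sorted value vector,
#' equal to the cross-column mean of order statistics; within-column rank
#' order is preserved and ties receive the mean of their target values.
#'
#' @param mat Numeric matrix, samples in columns, no missing values.
#' @return Matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2L) stop("need at least 2 columns", call. = FALSE)
  if (anyNA(mat)) stop("missing values are not supported", call. = FALSE)
  out <- limma::normalizeQuantiles(mat, ties = TRUE)
  dimnames(out) <- dimnames(mat)
  out
}

#' Average duplicate probes into one row per gene
#'
#' @param mat Probes x samples numeric matrix.
#' @param probe_to_gene Named character vector mapping every rowname of
#'   `mat` (probe) to a gene identifier.
#' @return Genes x samples matrix, one row per gene, values the arithmetic
#'   mean over that gene's probes; gene rows sorted by id.
#' @export
collapse_duplicates <- function(mat, probe_to_gene) {
  mat <- as.matrix(mat)
  probes <- rownames(mat)
  if (is.null(probes)) stop("matrix must have probe rownames", call. = FALSE)
  if (!all(probes %in% names(probe_to_gene))) {
    stop("probe-to-gene map must cover all probes", call. = FALSE)
  }
  genes <- probe_to_gene[probes]
  sums <- rowsum(mat, group = genes)
  counts <- as.vector(table(genes)[rownames(sums)])
  out <- sums / counts
  out[order(rownames(out)), , drop = FALSE]
}

#' Form log2 ratios against the vehicle control
#'
#' Intensities are floored at `floor` before division to guard against
#' degenerate near-zero values; the vehicle column is dropped from the
#' result (it is identically 0 on the ratio scale).
#'
#' @param mat Genes x samples matrix of normalized intensities.
#' @param vehicle Name of the vehicle-control column.
#' @param floor Intensity floor applied before the ratio.
#' @return Genes x (samples - 1) matrix of log2 ratios.
#' @export
log_ratio <- function(mat, vehicle = "vehicle", floor = 1) {
  mat <- as.matrix(mat)
  if (!vehicle %in% colnames(mat)) {
    stop(sprintf("vehicle column '%s' not found", vehicle), call. = FALSE)
  }
  mat <- pmax(mat, floor)
  if (any(mat <= 0)) {
    stop("non-positive intensities after flooring", call. = FALSE)
  }
  v <- mat[, vehicle]
  out <- log2(mat[, setdiff(colnames(mat), vehicle), drop = FALSE] / v)
  out
}

#' UPGMA (average-linkage) hierarchical clustering
#'
#' Agglomerative clustering where the inter-cluster distance is the
#' unweighted mean of pairwise distances, as in Gene Cluster 3.0's average
#' linkage.  The default distance is 1 - Pearson correlation.
#'
#' @param mat Numeric matrix; items on the chosen axis are clustered.
#' @param axis `"genes"` (rows) or `"samples"` (columns).
#' @param distance `"pearson"` (1 - correlation) or `"euclidean"`.
#' @return An [stats::hclust] object (merge tree plus deterministic leaf
#'   order).
#' @export
cluster_average_linkage <- function(mat, axis = c("genes", "samples"),
                                    distance = c("pearson", "euclidean")) {
  axis <- match.arg(axis)
  distance <- match.arg(distance)
  mat <- as.matrix(mat)
  x <- if (axis == "genes") mat else t(mat)
  if (nrow(x) < 2L) stop("need at least 2 items to cluster", call. = FALSE)
  if (distance == "pearson") {
    sds <- apply(x, 1, sd)
    if (any(sds == 0)) {
      bad <- rownames(x)[sds == 0]
      stop(sprintf("constant rows under correlation distance: %s",
                   paste(head(bad, 10), collapse = ", ")), call. = FALSE)
    }
    d <- as.dist(1 - cor(t(x)))
  } else {
    d <- dist(x)
  }
  hclust(d, method = "average")
}

#' Full preprocessing chain from raw intensities to log ratios
#'
#' Applies background filtering, quantile normalization, duplicate-probe
#' averaging and vehicle log-ratio formation in order, returning the
#' expression matrix plus a provenance record of per-stage counts.
#'
#' @param raw A `raw_intensity_table` whose first sample is the vehicle.
#' @param background_factor Signal/background retention threshold.
#' @param vehicle Vehicle-control sample name.
#' @param floor Intensity floor for ratio formation.
#' @return List with `expr` (genes x doses log2-ratio matrix) and
#'   `provenance` (probe/gene counts and the parameters used).
#' @export
preprocess_raw <- function(raw, background_factor = 1.4,
                           vehicle = "vehicle", floor = 1) {
  filtered <- filter_by_background(raw, background_factor)
  norm <- quantile_normalize(filtered$signal)
  map <- setNames(filtered$gene_id, filtered$probe_id)
  by_gene <- collapse_duplicates(norm, map)
  expr <- log_ratio(by_gene, vehicle = vehicle, floor = floor)
  list(expr = expr,
       provenance = list(
         n_probes_in = length(raw$probe_id),
         n_probes_kept = length(filtered$probe_id),
         n_genes = nrow(expr),
         background_factor = background_factor,
         intensity_floor = floor))
}
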