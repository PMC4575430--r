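# Functional network module detection: induced interaction subgraph over
# the dose-responsive genes, Markov clustering (expansion / inflation /
# pruning on the column-stochastic adjacency), and module filtering by
# size and expression coherence.

#' Build the induced interaction graph over a gene set
#'
#' Restricts an undirected weighted edge list to the supplied genes,
#' collapses duplicate edges to the maximum weight, and drops isolated
#' genes (reported via message).
#'
#' @param edges data.frame with columns `from`, `to` and optionally
#'   `weight` (default 1).
#' @param genes Gene identifiers to induce on.
#' @return An [igraph::graph] (undirected, weighted).
#' @export
build_graph <- function(edges, genes) {
  stopifnot(all(c("from", "to") %in% names(edges)))
  if (is.null(edges$weight)) edges$weight <- 1
  keep <- edges$from %in% genes & edges$to %in% genes &
    edges$from != edges$to
  edges <- edges[keep, , drop = FALSE]
  if (!nrow(edges)) {
    stop("no interactions among the supplied genes", call. = FALSE)
  }
  if (any(edges$weight <= 0)) {
    stop("edge weights must be positive", call. = FALSE)
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  g <- igraph::simplify(g, edge.attr.comb = list(weight = "max"))
  n_iso <- length(setdiff(genes, igraph::V(g)$name))
  if (n_iso > 0) {
    message(sprintf("%d isolated genes dropped from the network", n_iso))
  }
  g
}

#' Markov clustering of an interaction graph
#'
#' The standard MCL loop on the column-stochastic adjacency matrix (with
#' unit self-loops added): repeat expansion (matrix power), inflation
#' (elementwise power followed by column normalization) and pruning of
#' entries below `prune_threshold` until the maximum absolute change drops
#' below 1e-8 or `max_iter` is reached.  Clusters are read from the
#' converged non-zero structure; when attractor supports overlap, each
#' node follows its largest-mass attractor (ties to the lowest cluster
#' id).
#'
#' @param graph An [igraph::graph] from [build_graph()].
#' @param inflation Inflation exponent (> 1; default 5.0 gives
#'   fine-grained modules).
#' @param expansion Expansion power (default 2).
#' @param prune_threshold Entries below this are zeroed each iteration.
#' @param max_iter Iteration cap.
#' @return A `mcl_partition`: list with `membership` (named integer
#'   vector), `n_clusters`, `converged`.
#' @export
mcl <- function(graph, inflation = 5.0, expansion = 2,
                prune_threshold = 1e-5, max_iter = 100) {
  if (inflation <= 1) stop("inflation must exceed 1", call. = FALSE)
  A <- as.matrix(igraph::as_adjacency_matrix(graph, attr = "weight",
                                             sparse = TRUE))
  nodes <- rownames(A)
  diag(A) <- 1  # self-loops stabilize the flow
  M <- sweep(A, 2, colSums(A), "/")
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    prev <- M
    E <- M
    for (e in seq_len(expansion - 1)) E <- E %*% M
    E <- E^inflation
    E <- sweep(E, 2, colSums(E), "/")
    # prune on the normalized matrix so the threshold is a column fraction
    P <- E
    P[P < prune_threshold] <- 0
    dead <- colSums(P) == 0
    if (any(dead)) P[, dead] <- E[, dead]  # never empty a column
    M <- sweep(P, 2, colSums(P), "/")
    if (max(abs(M - prev)) < 1e-8) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("MCL did not converge within max_iter; returning current state")
  }
  # attractors: rows with surviving mass; a node joins the attractor row
  # holding the most of its column; attractor rows sharing support merge.
  support <- M > 0
  gg <- igraph::graph_from_adjacency_matrix(support | t(support),
                                            mode = "undirected")
  comp <- igraph::components(gg)$membership
  # renumber clusters by order of first appearance for determinism
  membership <- as.integer(factor(comp, levels = unique(comp)))
  names(membership) <- nodes
  structure(list(membership = membership,
                 n_clusters = max(membership),
                 converged = converged),
            class = "mcl_partition")
}

#' Filter modules by size and expression coherence
#'
#' Retains the clusters with at least `min_size` members whose mean
#' pairwise Pearson correlation of dose profiles is at least `min_corr`;
#' survivors are renumbered 0..m-1 by decreasing size (ties by first gene
#' id).  Constant-profile members contribute only their non-degenerate
#' pairs to the mean (reported via message).
#'
#' @param partition A `mcl_partition` (or named membership vector).
#' @param expr Genes x doses log2-ratio matrix.
#' @param min_size Minimum module size (default 7).
#' @param min_corr Minimum mean pairwise correlation (default 0.8).
#' @return A `module_set`: list with `members` (named list of gene
#'   vectors, names `"0" .. "m-1"`) and `summary` data.frame (module,
#'   size, mean_corr).
#' @export
filter_modules <- function(partition, expr, min_size = 7, min_corr = 0.8) {
  membership <- if (inherits(partition, "mcl_partition"))
    partition$membership else partition
  expr <- as.matrix(expr)
  present <- names(membership) %in% rownames(expr)
  if (!all(present)) {
    message(sprintf("%d cluster members missing from the matrix, dropped",
                    sum(!present)))
    membership <- membership[present]
  }
  clusters <- split(names(membership), membership)
  stats_ <- lapply(clusters, function(genes) {
    if (length(genes) < 2) {
      return(list(size = length(genes), mean_corr = NA_real_))
    }
    x <- expr[genes, , drop = FALSE]
    sds <- apply(x, 1, sd)
    if (any(sds == 0)) {
      message(sprintf("module with %d constant-profile member(s); %s",
                      sum(sds == 0),
                      "correlations computed over non-degenerate pairs"))
    }
    ok <- sds > 0
    if (sum(ok) < 2) {
      return(list(size = length(genes), mean_corr = NA_real_))
    }
    cc <- cor(t(x[ok, , drop = FALSE]))
    list(size = length(genes),
         mean_corr = mean(cc[upper.tri(cc)]))
  })
  size <- vapply(stats_, `[[`, numeric(1), "size")
  mcorr <- vapply(stats_, `[[`, numeric(1), "mean_corr")
  keep <- which(size >= min_size & !is.na(mcorr) & mcorr >= min_corr)
  ord <- keep[order(-size[keep],
                    vapply(clusters[keep], min, character(1)))]
  members <- clusters[ord]
  names(members) <- as.character(seq_along(members) - 1L)
  structure(list(members = members,
                 summary = data.frame(
                   module = names(members),
                   size = size[ord],
                   mean_corr = mcorr[ord],
                   row.names = NULL, stringsAsFactors = FALSE)),
            class = "module_set")
}
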