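# Over-representation analysis with the hypergeometric tail, its EASE
# ("modified Fisher's exact") variant, and Benjamini-Hochberg adjustment;
# reused for GO-style sets, pathway sets, and per-module enrichment.

#' Hypergeometric upper-tail p-value (Fisher / EASE variants)
#'
#' `fisher` returns `P(X >= x)` under `Hypergeometric(N, K, k)`; `ease`
#' returns `P(X >= max(x - 1, 0))`, the conservative EASE score that
#' penalizes single-gene overlaps.  `x = 0` (and `ease` with `x <= 1`)
#' gives p = 1.
#'
#' @param N Universe size.
#' @param K Gene-set size.
#' @param k Query size.
#' @param x Overlap between query and set.
#' @param variant `"fisher"` or `"ease"`.
#' @return p-value in (0, 1].
#' @export
hypergeom_tail <- function(N, K, k, x, variant = c("fisher", "ease")) {
  variant <- match.arg(variant)
  if (!(x >= 0 && x <= min(K, k) && K <= N && k <= N)) {
    stop("inconsistent counts: need 0 <= x <= min(K, k) <= N",
         call. = FALSE)
  }
  thr <- if (variant == "ease") max(x - 1, 0) else x
  phyper(thr - 1, K, N - K, k, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted values `min_{j: p_j >= p_i} m p_j / rank_j`, capped at
#' 1; rejecting at `adjusted <= alpha` reproduces the classical BH rule.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Adjusted values, same order as the input.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(p, method = "BH")
}

#' Over-representation of a query gene list against a collection
#'
#' Tests every set in the collection against the query with
#' [hypergeom_tail()], using the collection's universe as background, and
#' adjusts across the whole collection with Benjamini-Hochberg.  Query
#' genes outside the universe are dropped (with a message).
#'
#' @param query Gene-identifier vector.
#' @param collection A `gene_set_collection`.
#' @param variant `"ease"` (default, the DAVID-style modified Fisher test)
#'   or `"fisher"`.
#' @return data.frame sorted by p with columns set_id, name, N, K, k, x,
#'   p, fdr.
#' @export
enrich <- function(query, collection, variant = c("ease", "fisher")) {
  variant <- match.arg(variant)
  stopifnot(inherits(collection, "gene_set_collection"))
  universe <- collection$universe
  dropped <- setdiff(query, universe)
  if (length(dropped)) {
    message(sprintf("dropped %d query genes outside the universe",
                    length(dropped)))
  }
  query <- unique(intersect(query, universe))
  if (!length(query)) {
    stop("query is empty after universe intersection", call. = FALSE)
  }
  N <- length(universe)
  k <- length(query)
  rows <- lapply(seq_along(collection$sets), function(i) {
    s <- collection$sets[[i]]
    K <- length(s)
    x <- length(intersect(s, query))
    data.frame(set_id = i, name = names(collection$sets)[i],
               N = N, K = K, k = k, x = x,
               p = hypergeom_tail(N, K, k, x, variant),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_adjust(out$p)
  out <- out[order(out$p, out$name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-module over-representation
#'
#' Applies [enrich()] to each module's member genes, with the BH family
#' being the collection tested within that module.
#'
#' @param modules A `module_set` (see [filter_modules()]) or a named list
#'   of gene vectors.
#' @param collection A `gene_set_collection`.
#' @param variant Passed to [enrich()].
#' @return Named list of enrichment tables, one per module.
#' @export
enrich_modules <- function(modules, collection,
                           variant = c("ease", "fisher")) {
  members <- if (inherits(modules, "module_set")) modules$members else
    modules
  lapply(members, enrich, collection = collection,
         variant = match.arg(variant))
}
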