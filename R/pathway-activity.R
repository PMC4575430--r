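# Signed pathway-activity scoring: per-sample activity is the
# size-normalized sum of member-gene log2 ratios with weight -1 for
# repressors, so that repression contributes to, rather than cancels, the
# accumulated pathway effect.  Significance via gene-label permutation.

#' Derive repressor roles from a pathway topology
#'
#' A gene whose outgoing edges are majority repressions (-1) is treated as
#' a repressor (weight -1) for its pathway; all other genes get +1.
#'
#' @param graph A `pathway_graph`.
#' @return Named vector of weights in \{+1, -1\} over the pathway genes.
#' @export
repressor_roles <- function(graph) {
  stopifnot(inherits(graph, "pathway_graph"))
  w <- setNames(rep(1, length(graph$genes)), graph$genes)
  if (nrow(graph$edges)) {
    bal <- tapply(graph$edges$sign, graph$edges$from, sum)
    w[names(bal)[bal < 0]] <- -1
  }
  w
}

#' Per-sample pathway activity
#'
#' `A_p(sample) = (1 / |pathway ∩ measured|) * sum_g w_g x_g(sample)` with
#' `x` the log2 ratio and `w_g = -1` for repressors, `+1` otherwise (genes
#' absent from `roles` default to +1).  Unmeasured members are excluded
#' (reported via message).
#'
#' @param expr Genes x samples log2-ratio matrix.
#' @param pathway Member gene identifiers.
#' @param roles Optional named weight vector in \{+1, -1\}.
#' @return Named numeric vector of per-sample activities.
#' @export
pathway_activity <- function(expr, pathway, roles = NULL) {
  expr <- as.matrix(expr)
  pathway <- unique(pathway)
  measured <- intersect(pathway, rownames(expr))
  if (!length(measured)) {
    stop("no pathway members are measured in the expression matrix",
         call. = FALSE)
  }
  if (length(measured) < length(pathway)) {
    message(sprintf("%d pathway members unmeasured, excluded",
                    length(pathway) - length(measured)))
  }
  w <- setNames(rep(1, length(measured)), measured)
  if (!is.null(roles)) {
    known <- intersect(measured, names(roles))
    w[known] <- roles[known]
  }
  if (!all(w %in% c(-1, 1))) {
    stop("role weights must be +1 or -1", call. = FALSE)
  }
  colSums(w * expr[measured, , drop = FALSE]) / length(measured)
}

#' Pathway activities with permutation FDR
#'
#' Computes each pathway's per-sample activity profile and assesses it
#' against a null built by permuting the matrix's gene labels `n_perm`
#' times.  The per-pathway statistic is the maximum over samples of |A_p|;
#' the permutation p-value `(#\{null >= observed\} + 1)/(n_perm + 1)` is
#' then Benjamini-Hochberg adjusted across pathways.
#'
#' @param expr Genes x samples log2-ratio matrix.
#' @param pathways Named list of member-gene vectors (or a
#'   `gene_set_collection`, whose sets are used).
#' @param roles Optional named list of role-weight vectors, parallel to
#'   `pathways` (entries may be NULL for all-activator pathways).
#' @param n_perm Number of gene-label permutations (default 1000).
#' @param seed RNG seed.
#' @return An `activity_result`: list with `activity` (pathway x sample
#'   matrix), `table` (pathway, stat, p, fdr), `n_perm`.
#' @export
activity_fdr <- function(expr, pathways, roles = NULL, n_perm = 1000,
                         seed = 1) {
  expr <- as.matrix(expr)
  if (inherits(pathways, "gene_set_collection")) pathways <- pathways$sets
  stopifnot(length(pathways) > 0, !is.null(names(pathways)))
  n_perm <- check_count(n_perm, "n_perm", min = 1L)
  act <- t(vapply(seq_along(pathways), function(i) {
    pathway_activity(expr, pathways[[i]], roles[[names(pathways)[i]]])
  }, numeric(ncol(expr))))
  dimnames(act) <- list(names(pathways), colnames(expr))
  observed <- apply(abs(act), 1, max)
  exceed <- numeric(length(pathways))
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      perm <- expr[sample.int(nrow(expr)), , drop = FALSE]
      rownames(perm) <- rownames(expr)
      stat_b <- vapply(seq_along(pathways), function(i) {
        max(abs(suppressMessages(
          pathway_activity(perm, pathways[[i]],
                           roles[[names(pathways)[i]]]))))
      }, numeric(1))
      exceed <- exceed + (stat_b >= observed)
    }
  })
  p <- (exceed + 1) / (n_perm + 1)
  tab <- data.frame(pathway = names(pathways), stat = observed, p = p,
                    fdr = bh_adjust(p), row.names = NULL,
                    stringsAsFactors = FALSE)
  structure(list(activity = act, table = tab, n_perm = n_perm),
            class = "activity_result")
}
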