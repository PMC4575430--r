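# Topology-aware pathway impact analysis.  Two evidences per pathway: an
# over-representation tail (P_NDE) and a perturbation evidence (P_PERT)
# from propagating differential expression through the signed topology,
# combined into a global p-value and adjusted across pathways.

# Propagation matrix B with B[v, u] = sign(u -> v) / N_ds(u), where N_ds
# is u's number of downstream targets; multiple parallel edges sum.
beta_matrix <- function(graph) {
  genes <- graph$genes
  m <- length(genes)
  B <- matrix(0, m, m, dimnames = list(genes, genes))
  e <- graph$edges
  if (nrow(e)) {
    nds <- table(factor(e$from, levels = genes))
    for (i in seq_len(nrow(e))) {
      B[e$to[i], e$from[i]] <- B[e$to[i], e$from[i]] +
        e$sign[i] / nds[[e$from[i]]]
    }
  }
  B * graph$damping
}

#' Propagate differential expression through a pathway topology
#'
#' Solves the perturbation system `PF(v) = dE(v) + sum_{u->v} beta_uv
#' PF(u) / N_ds(u)`; the net accumulation is `Acc = PF - dE` and the total
#' accumulated perturbation `tA = sum_v Acc(v)`.
#'
#' @param graph A `pathway_graph`.
#' @param de Named vector of log2 fold-changes over (a subset of) the
#'   pathway genes; missing genes count as 0.
#' @return List with `pf`, `acc` (named vectors) and `ta` (scalar).
#' @export
perturbation <- function(graph, de) {
  stopifnot(inherits(graph, "pathway_graph"))
  genes <- graph$genes
  dE <- setNames(numeric(length(genes)), genes)
  known <- intersect(names(de), genes)
  dE[known] <- de[known]
  M <- diag(length(genes)) - beta_matrix(graph)
  if (rcond(M) < 1e-10) {
    stop(paste("perturbation system is singular;",
               "consider damping the edge weights"), call. = FALSE)
  }
  pf <- drop(solve(M, dE))
  names(pf) <- genes
  acc <- pf - dE
  list(pf = pf, acc = acc, ta = sum(acc))
}

# Coefficient vector c with tA = sum(c * dE): tA = 1'(M^-1 - I) dE.
ta_coefficients <- function(graph) {
  M <- diag(length(graph$genes)) - beta_matrix(graph)
  if (rcond(M) < 1e-10) {
    stop("perturbation system is singular", call. = FALSE)
  }
  setNames(colSums(solve(M)) - 1, graph$genes)
}

#' Over-representation evidence for a pathway
#'
#' Plain hypergeometric upper tail `P(X >= x)` for observing `x`
#' differentially expressed genes on a pathway of size `K` given `k` DE
#' genes in a universe of `N`.
#'
#' @param x DE genes on the pathway.
#' @param K Pathway size (measured members).
#' @param N Universe size.
#' @param k Total DE genes.
#' @return P_NDE in (0, 1].
#' @export
p_nde <- function(x, K, N, k) {
  hypergeom_tail(N, K, k, x, variant = "fisher")
}

#' Bootstrap perturbation evidence
#'
#' Re-assigns `n_de` log fold-changes sampled with replacement from
#' `de_pool` to randomly chosen pathway genes `n_boot` times, recomputes
#' the total accumulation, and returns the two-sided median-centered
#' p-value `(#\{|tA_null - med| >= |tA_obs - med|\} + 1)/(n_boot + 1)`.
#' Pathways with no DE genes return 1 by convention.
#'
#' @param graph A `pathway_graph`.
#' @param ta_obs Observed total accumulation.
#' @param de_pool Pool of available log fold-changes to resample.
#' @param n_de Number of DE genes on the pathway.
#' @param n_boot Bootstrap replicates (default 3000).
#' @param seed RNG seed.
#' @return P_PERT in (0, 1].
#' @export
p_pert <- function(graph, ta_obs, de_pool, n_de, n_boot = 3000, seed = 1) {
  if (!length(de_pool)) stop("de_pool is empty", call. = FALSE)
  n_de <- check_count(n_de, "n_de")
  if (n_de == 0L) return(1)
  n_boot <- check_count(n_boot, "n_boot", min = 1L)
  cvec <- ta_coefficients(graph)
  m <- length(cvec)
  ta_null <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(m, min(n_de, m))
      sum(cvec[idx] * sample(de_pool, length(idx), replace = TRUE))
    }, numeric(1))
  })
  med <- stats::median(ta_null)
  (sum(abs(ta_null - med) >= abs(ta_obs - med)) + 1) / (n_boot + 1)
}

#' Combine the two pathway evidences into a global p-value
#'
#' Fisher-product combination for two independent uniforms:
#' `c = P_NDE * P_PERT`, `P_G = c - c ln(c)`.
#'
#' @param p_nde,p_pert Evidences in (0, 1].
#' @return P_G in (0, 1].
#' @export
combine_global <- function(p_nde, p_pert) {
  stopifnot(p_nde > 0, p_nde <= 1, p_pert > 0, p_pert <= 1)
  cc <- p_nde * p_pert
  cc - cc * log(cc)
}

#' Run the pathway impact analysis over a set of topologies
#'
#' The differential-expression input is a named vector of log2
#' fold-changes (typically the union of the significant dose patterns at
#' the highest dose).  For each pathway the over-representation tail, the
#' propagation-based perturbation evidence and the combined global
#' p-value are computed; global p-values are BH-adjusted across pathways
#' and flagged at 0.01 and 0.05.
#'
#' @param de Named log2 fold-change vector of the DE genes.
#' @param universe All measured gene identifiers.
#' @param topologies Named list of `pathway_graph` objects.
#' @param n_boot Bootstrap replicates per pathway (default 3000).
#' @param seed RNG seed.
#' @return data.frame with columns pathway, size, n_de, ta, p_nde,
#'   p_pert, p_g, p_gfdr, sig01, sig05, sorted by p_g.
#' @export
run_spia <- function(de, universe, topologies, n_boot = 3000, seed = 1) {
  stopifnot(length(topologies) > 0, !is.null(names(topologies)))
  de <- de[names(de) %in% universe]
  if (!length(de)) stop("no DE genes in the universe", call. = FALSE)
  seeds <- derive_seeds(seed, length(topologies))
  rows <- lapply(seq_along(topologies), function(i) {
    g <- topologies[[i]]
    members <- intersect(g$genes, universe)
    de_in <- intersect(names(de), members)
    pert <- perturbation(g, de[de_in])
    pn <- p_nde(length(de_in), length(members), length(universe),
                length(de))
    pp <- p_pert(g, pert$ta, de_pool = de, n_de = length(de_in),
                 n_boot = n_boot, seed = seeds[i])
    data.frame(pathway = names(topologies)[i], size = length(members),
               n_de = length(de_in), ta = pert$ta, p_nde = pn,
               p_pert = pp, p_g = combine_global(pn, pp),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_gfdr <- bh_adjust(out$p_g)
  out$sig01 <- out$p_gfdr < 0.01
  out$sig05 <- out$p_gfdr < 0.05
  out <- out[order(out$p_g, out$pathway), , drop = FALSE]
  rownames(out) <- NULL
  out
}
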