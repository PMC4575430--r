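# Synthetic-data generators with planted ground truth.
#
# Every input the analysis chain consumes can be simulated here: a
# dose-series expression matrix with reciprocal dose-monotone gene blocks
# (a down-regulated "metabolism-like" block and an up-regulated
# "signaling-like" block on a null background), a reference compendium of
# rank-ordered instances containing known mimics and decoys, gene-set
# collections with planted enrichment, and signed directed pathway
# topologies.

#' Simulation configuration for a planted dose series
#'
#' @param n_genes Number of genes in the universe.
#' @param n_doses Number of treatment doses beyond the vehicle control.
#' @param frac_up,frac_down Fractions of the universe planted as
#'   dose-monotone up- / down-regulated blocks; must sum to at most 1.
#' @param effect_size Mean log2-ratio increment per dose step for planted
#'   genes (positive for the up block, negated for the down block).
#' @param noise_sd Standard deviation of i.i.d. additive Gaussian noise on
#'   the log2 scale.
#' @param seed Integer RNG seed; identical configurations produce
#'   bit-identical output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 1000, n_doses = 3, frac_up = 0.2,
                       frac_down = 0.3, effect_size = 1, noise_sd = 0.1,
                       seed = 1) {
  n_genes <- check_count(n_genes, "n_genes", min = 1L)
  n_doses <- check_count(n_doses, "n_doses", min = 2L)
  check_fraction(frac_up, "frac_up")
  check_fraction(frac_down, "frac_down")
  if (frac_up + frac_down > 1) {
    stop("frac_up + frac_down must not exceed 1", call. = FALSE)
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    stop("noise_sd must be non-negative", call. = FALSE)
  }
  structure(list(n_genes = n_genes, n_doses = n_doses, frac_up = frac_up,
                 frac_down = frac_down, effect_size = effect_size,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a planted dose-series expression matrix
#'
#' Produces a genes x doses matrix of log2 treated/vehicle ratios.  Planted
#' up-genes have expected value `+effect_size * dose_index`, down-genes the
#' negative, null genes 0; Gaussian noise of sd `noise_sd` is added i.i.d.
#' The vehicle column (identically 0 by construction) is not materialized.
#'
#' @param config A [sim_config()].
#' @return A list with `expr` (numeric matrix, rownames = gene ids, colnames
#'   `d1..dn`) and `truth` (a `planted_truth` object partitioning the
#'   universe into `up_genes`, `down_genes`, `null_genes`).
#' @export
generate_dose_series <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_genes
  d <- config$n_doses
  genes <- sprintf("g%05d", seq_len(n))
  n_up <- round(config$frac_up * n)
  n_down <- round(config$frac_down * n)
  with_seed(config$seed, {
    idx <- sample.int(n)
    up <- sort(genes[idx[seq_len(n_up)]])
    down <- sort(genes[idx[n_up + seq_len(n_down)]])
    direction <- setNames(numeric(n), genes)
    direction[up] <- 1
    direction[down] <- -1
    mu <- outer(direction, seq_len(d)) * config$effect_size
    noise <- matrix(rnorm(n * d, sd = config$noise_sd), n, d)
    expr <- mu + noise
    dimnames(expr) <- list(genes, paste0("d", seq_len(d)))
    truth <- planted_truth(up_genes = up, down_genes = down,
                           null_genes = setdiff(genes, c(up, down)))
    list(expr = expr, truth = truth)
  })
}

#' Planted ground truth
#'
#' @param up_genes,down_genes,null_genes Disjoint gene-identifier vectors
#'   that together partition the simulated universe.
#' @param mimic_instances Identifiers of compendium instances sharing the
#'   planted signature (filled in by [generate_reference_compendium()]).
#' @export
planted_truth <- function(up_genes, down_genes, null_genes,
                          mimic_instances = character(0)) {
  all <- c(up_genes, down_genes, null_genes)
  if (anyDuplicated(all)) {
    stop("up/down/null gene sets must be disjoint", call. = FALSE)
  }
  structure(list(up_genes = up_genes, down_genes = down_genes,
                 null_genes = null_genes,
                 mimic_instances = mimic_instances),
            class = "planted_truth")
}

truth_universe <- function(truth) {
  sort(c(truth$up_genes, truth$down_genes, truth$null_genes))
}

#' Emit probe-level raw intensities from a log-ratio matrix
#'
#' Exponentiates a planted log2-ratio matrix into a probe-level intensity
#' table with a vehicle channel, duplicate spots per gene, and a local
#' background channel, so the full preprocessing path (background filtering,
#' quantile normalization, duplicate collapsing, ratio formation) can be
#' exercised.  A fraction of probes is emitted near background level to give
#' the background filter something to remove.
#'
#' @param expr Log2-ratio matrix from [generate_dose_series()].
#' @param probes_per_gene Duplicate spots per gene.
#' @param base_intensity Vehicle-channel mean intensity.
#' @param background_level Local background mean intensity.
#' @param frac_low Fraction of probes emitted at background level (failing a
#'   1.4-fold background filter).
#' @param seed RNG seed.
#' @return A `raw_intensity_table`: list with `probe_id`, `gene_id`,
#'   `signal` and `background` matrices (probes x samples, first sample
#'   `vehicle`).
#' @export
generate_raw_intensities <- function(expr, probes_per_gene = 2,
                                     base_intensity = 1000,
                                     background_level = 100,
                                     frac_low = 0.05, seed = 1) {
  genes <- rownames(expr)
  n <- length(genes)
  p <- n * probes_per_gene
  samples <- c("vehicle", colnames(expr))
  with_seed(seed, {
    gene_id <- rep(genes, each = probes_per_gene)
    probe_id <- sprintf("%s_p%d", gene_id, rep(seq_len(probes_per_gene), n))
    ratios <- 2^expr[gene_id, , drop = FALSE]
    base <- base_intensity * exp(rnorm(p, sd = 0.1))
    signal <- cbind(base, base * ratios)
    colnames(signal) <- samples
    low <- runif(p) < frac_low
    signal[low, ] <- background_level *
      matrix(runif(sum(low) * length(samples), 0.8, 1.3), sum(low))
    background <- matrix(background_level * exp(rnorm(p * length(samples),
                                                      sd = 0.05)),
                         p, length(samples), dimnames = list(NULL, samples))
    raw_intensity_table(probe_id, gene_id, signal, background)
  })
}

#' Raw probe-level intensity table
#' @param probe_id,gene_id Parallel identifier vectors; probe ids unique.
#' @param signal,background Non-negative probes x samples matrices.
#' @export
raw_intensity_table <- function(probe_id, gene_id, signal, background) {
  if (anyDuplicated(probe_id)) stop("probe ids must be unique", call. = FALSE)
  if (any(signal < 0) || any(background < 0)) {
    stop("intensities must be non-negative", call. = FALSE)
  }
  rownames(signal) <- probe_id
  rownames(background) <- probe_id
  structure(list(probe_id = probe_id, gene_id = gene_id, signal = signal,
                 background = background), class = "raw_intensity_table")
}

#' Generate a rank-ordered reference compendium with planted mimics
#'
#' Each instance is a complete rank-ordering of the gene universe from most
#' up-regulated (rank 1) to most down-regulated (rank n).  Mimic instances
#' sort on `planted signature value + N(0, rank_noise_sd)` so that planted
#' up-genes land near the top and down-genes near the bottom; decoys are
#' uniform random permutations; a fraction of mimics can be sign-flipped
#' into anti-mimics to exercise negative connectivity.
#'
#' @param truth A `planted_truth`.
#' @param n_instances Total number of instances.
#' @param n_mimics Number of instances sharing the planted signature.
#' @param inversion_fraction Fraction of mimics emitted sign-flipped.
#' @param rank_noise_sd Gaussian sd of the mimic sorting score (0 = perfect
#'   retrieval, large = random).
#' @param seed RNG seed.
#' @return A `reference_compendium`: list with `rank_matrix` (genes x
#'   instances integer ranks), `instances` metadata data.frame,
#'   `universe`, `mimic_instances`, `anti_instances`.
#' @export
generate_reference_compendium <- function(truth, n_instances, n_mimics,
                                          inversion_fraction = 0,
                                          rank_noise_sd = 0.25, seed = 1) {
  universe <- truth_universe(truth)
  n <- length(universe)
  if (n == 0L) stop("gene universe is empty", call. = FALSE)
  n_instances <- check_count(n_instances, "n_instances", min = 1L)
  n_mimics <- check_count(n_mimics, "n_mimics")
  if (n_mimics > n_instances) {
    stop("n_mimics must not exceed n_instances", call. = FALSE)
  }
  check_fraction(inversion_fraction, "inversion_fraction")
  sig <- setNames(numeric(n), universe)
  sig[truth$up_genes] <- 1
  sig[truth$down_genes] <- -1
  n_anti <- round(inversion_fraction * n_mimics)
  ids <- sprintf("inst%03d", seq_len(n_instances))
  kind <- c(rep("mimic", n_mimics - n_anti), rep("anti", n_anti),
            rep("decoy", n_instances - n_mimics))
  with_seed(seed, {
    rank_matrix <- matrix(0L, n, n_instances,
                          dimnames = list(universe, ids))
    for (i in seq_len(n_instances)) {
      score <- switch(kind[i],
        mimic = sig + rnorm(n, sd = rank_noise_sd),
        anti  = -sig + rnorm(n, sd = rank_noise_sd),
        decoy = runif(n))
      # rank 1 = most up-regulated; ties broken by gene id for determinism
      ord <- order(-score, universe)
      rank_matrix[ord, i] <- seq_len(n)
    }
    instances <- data.frame(
      instance_id = ids,
      compound = ifelse(kind == "mimic", "planted_mimic",
                        ifelse(kind == "anti", "planted_inverse",
                               paste0("decoy_", ids))),
      cell_line = "SYN1",
      dose = "d1",
      stringsAsFactors = FALSE)
    structure(list(rank_matrix = rank_matrix, instances = instances,
                   universe = universe,
                   mimic_instances = ids[kind == "mimic"],
                   anti_instances = ids[kind == "anti"]),
              class = "reference_compendium")
  })
}

#' Generate a gene-set collection with planted enrichment
#'
#' Designated enriched sets draw at least 80 percent (by default 90) of
#' their members from the corresponding planted block; background sets draw
#' uniformly from the universe.
#'
#' @param truth A `planted_truth`.
#' @param n_sets Total number of sets.
#' @param set_size Length-2 integer range of set sizes (inclusive).
#' @param n_enriched_up,n_enriched_down Numbers of sets planted as enriched
#'   in the up / down block.
#' @param purity Fraction of an enriched set drawn from its block.
#' @param seed RNG seed.
#' @return A `gene_set_collection`: list with `sets` (named list of gene
#'   vectors) and `universe`.
#' @export
generate_gene_sets <- function(truth, n_sets, set_size = c(10, 30),
                               n_enriched_up = 1, n_enriched_down = 1,
                               purity = 0.9, seed = 1) {
  universe <- truth_universe(truth)
  n_sets <- check_count(n_sets, "n_sets")
  if (n_enriched_up + n_enriched_down > n_sets) {
    stop("requested enriched sets exceed n_sets", call. = FALSE)
  }
  if (max(set_size) > length(universe)) {
    stop("set sizes must not exceed the universe size", call. = FALSE)
  }
  if (purity < 0.8) {
    stop("enriched-set purity below 0.8 defeats the planted design",
         call. = FALSE)
  }
  blocks <- c(rep("up", n_enriched_up), rep("down", n_enriched_down),
              rep("bg", n_sets - n_enriched_up - n_enriched_down))
  with_seed(seed, {
    sets <- vector("list", n_sets)
    names(sets) <- ifelse(
      blocks == "bg", sprintf("background_%03d", seq_len(n_sets)),
      sprintf("%s_enriched_%03d", blocks, seq_len(n_sets)))
    for (i in seq_len(n_sets)) {
      size <- if (set_size[1] == set_size[2]) set_size[1] else
        sample(seq(set_size[1], set_size[2]), 1)
      if (blocks[i] == "bg") {
        sets[[i]] <- sort(sample(universe, size))
      } else {
        block <- if (blocks[i] == "up") truth$up_genes else truth$down_genes
        n_in <- min(ceiling(purity * size), length(block))
        inside <- sample(block, n_in)
        outside <- sample(setdiff(universe, inside), size - n_in)
        sets[[i]] <- sort(c(inside, outside))
      }
    }
    gene_set_collection(sets, universe)
  })
}

#' Gene-set collection container
#' @param sets Named list of gene-identifier vectors.
#' @param universe Background gene list; members outside it are dropped
#'   (count reported via message).
#' @export
gene_set_collection <- function(sets, universe) {
  if (length(sets) && is.null(names(sets))) {
    stop("sets must be named", call. = FALSE)
  }
  dropped <- 0L
  sets <- lapply(sets, function(s) {
    keep <- s %in% universe
    dropped <<- dropped + sum(!keep)
    s[keep]
  })
  if (dropped > 0L) {
    message(sprintf("dropped %d set members absent from the universe",
                    dropped))
  }
  if (any(lengths(sets) == 0L) && length(sets)) {
    stop("gene sets must be non-empty after universe intersection",
         call. = FALSE)
  }
  structure(list(sets = sets, universe = universe),
            class = "gene_set_collection")
}

#' Generate a random signed directed pathway topology
#'
#' Each ordered pair of distinct members becomes an edge with probability
#' `edge_density`; each edge is a repression (-1) with probability
#' `repressor_fraction`, else an activation (+1).  Draws are repeated until
#' the perturbation linear system (I - B) of the impact analysis is
#' well-conditioned; as a last resort edge weights are damped.
#'
#' @param members Gene identifiers (at least 2).
#' @param edge_density Probability of each ordered pair being an edge.
#' @param repressor_fraction Probability that an edge is a repression.
#' @param seed RNG seed.
#' @param max_tries Redraws allowed before damping.
#' @return A `pathway_graph`: list with `genes` and an `edges` data.frame
#'   (`from`, `to`, `sign`).
#' @export
generate_pathway_topology <- function(members, edge_density = 0.15,
                                      repressor_fraction = 0.3, seed = 1,
                                      max_tries = 20) {
  if (length(members) < 2L) stop("need at least 2 members", call. = FALSE)
  check_fraction(edge_density, "edge_density")
  check_fraction(repressor_fraction, "repressor_fraction")
  pairs <- expand.grid(from = members, to = members,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  with_seed(seed, {
    for (try in seq_len(max_tries)) {
      keep <- runif(nrow(pairs)) < edge_density
      edges <- pairs[keep, , drop = FALSE]
      edges$sign <- ifelse(runif(nrow(edges)) < repressor_fraction, -1, 1)
      rownames(edges) <- NULL
      g <- pathway_graph(members, edges)
      if (pathway_solvable(g)) return(g)
    }
    warning("could not draw a well-conditioned topology; damping edges by 0.99")
    g$damping <- 0.99
    g
  })
}

#' Signed directed pathway graph
#' @param genes Member gene identifiers.
#' @param edges data.frame with columns `from`, `to`, `sign` (+1/-1);
#'   self-loops are dropped (they do not contribute to propagation).
#' @export
pathway_graph <- function(genes, edges) {
  stopifnot(all(c("from", "to", "sign") %in% names(edges)))
  if (!all(edges$sign %in% c(-1, 1))) {
    stop("edge signs must be +1 or -1", call. = FALSE)
  }
  if (!all(edges$from %in% genes) || !all(edges$to %in% genes)) {
    stop("edge endpoints must be pathway members", call. = FALSE)
  }
  edges <- edges[edges$from != edges$to, , drop = FALSE]
  structure(list(genes = genes, edges = edges, damping = 1),
            class = "pathway_graph")
}

# TRUE when (I - B) is comfortably invertible for the propagation solve.
pathway_solvable <- function(graph, tol = 1e-8) {
  M <- diag(length(graph$genes)) - beta_matrix(graph)
  rcond(M) > tol
}

#' Generate a planted-partition functional interaction network
#'
#' Builds an undirected interaction edge list over the dose-responsive
#' planted genes.  Each expression block (up, down) is carved into
#' functional sub-modules of about `module_size` genes; pairs within a
#' sub-module are connected with probability `p_within`, all other pairs
#' with probability `p_between`.  This emulates the community structure a
#' curated functional-interaction database contributes, with co-expression
#' coherence guaranteed inside every module (modules never straddle the
#' two reciprocal blocks).
#'
#' @param truth A `planted_truth`.
#' @param module_size Target planted module size.
#' @param p_within,p_between Edge probabilities within / between modules.
#' @param seed RNG seed.
#' @return data.frame with columns `from`, `to`, `weight`.
#' @export
generate_interaction_network <- function(truth, module_size = 30,
                                         p_within = 0.9,
                                         p_between = 0.01, seed = 1) {
  genes <- c(truth$up_genes, truth$down_genes)
  n <- length(genes)
  if (n < 2L) stop("need at least 2 pattern genes", call. = FALSE)
  carve <- function(k) {
    m <- max(1L, round(k / module_size))
    sort(rep_len(seq_len(m), k))
  }
  with_seed(seed, {
    module <- setNames(character(n), genes)
    # membership drawn independently of gene order, within each block
    module[sample(truth$up_genes)] <-
      paste0("u", carve(length(truth$up_genes)))
    module[sample(truth$down_genes)] <-
      paste0("d", carve(length(truth$down_genes)))
    module <- module[genes]
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    same <- module[idx[, 1]] == module[idx[, 2]]
    p <- ifelse(same, p_within, p_between)
    keep <- runif(nrow(idx)) < p
    data.frame(from = genes[idx[keep, 1]], to = genes[idx[keep, 2]],
               weight = 1, stringsAsFactors = FALSE)
  })
}
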