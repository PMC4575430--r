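# Independent oracles used to check the package implementations on small
# instances.  These deliberately take different computational paths from
# the functions they validate.

# Exhaustive step-function scan of the two-sided KS tag statistic: walk
# every rank position, tracking the tag empirical CDF, and take the two
# maxima from the full scan rather than from the tag positions only.
ks_oracle <- function(tag_ranks, n) {
  t <- length(tag_ranks)
  in_tags <- seq_len(n) %in% tag_ranks
  ft <- cumsum(in_tags) / t        # tag CDF at position i
  a <- max(ft - seq_len(n) / n)
  b <- max(seq_len(n) / n - c(0, ft[-n]))
  if (a > b) a else -b
}

# Classical BH step-up: find the largest rank with p <= rank * alpha / m.
bh_stepup_reject <- function(p, alpha) {
  m <- length(p)
  ord <- order(p)
  ok <- which(p[ord] <= seq_len(m) * alpha / m)
  rej <- logical(m)
  if (length(ok)) rej[ord[seq_len(max(ok))]] <- TRUE
  rej
}

# BH adjusted values by explicit min-over-larger-p construction.
bh_oracle <- function(p) {
  m <- length(p)
  vapply(seq_along(p), function(i) {
    larger <- which(p >= p[i])
    min(1, min(m * p[larger] / rank(p, ties.method = "max")[larger]))
  }, numeric(1))
}

# Hypergeometric upper tail by explicit pmf summation with choose().
hyper_oracle <- function(N, K, k, x) {
  if (x <= 0) return(1)
  i <- seq(x, min(K, k))
  sum(choose(K, i) * choose(N - K, k - i)) / choose(N, k)
}

# Damped Jacobi iteration for the pathway perturbation factors.
jacobi_pf <- function(graph, de, damp = 1, tol = 1e-10, max_iter = 10000) {
  genes <- graph$genes
  dE <- setNames(numeric(length(genes)), genes)
  dE[intersect(names(de), genes)] <- de[intersect(names(de), genes)]
  B <- dosesig:::beta_matrix(graph) * damp
  pf <- dE
  for (i in seq_len(max_iter)) {
    nxt <- dE + drop(B %*% pf)
    if (max(abs(nxt - pf)) < tol) return(nxt)
    pf <- nxt
  }
  nxt
}

# Random DAG pathway: edges only from lower to higher node index.
random_dag <- function(n_nodes, p_edge, repressor_fraction, seed) {
  set.seed(seed)
  genes <- sprintf("n%02d", seq_len(n_nodes))
  idx <- which(upper.tri(matrix(0, n_nodes, n_nodes)), arr.ind = TRUE)
  keep <- runif(nrow(idx)) < p_edge
  edges <- data.frame(from = genes[idx[keep, 1]], to = genes[idx[keep, 2]],
                      sign = ifelse(runif(sum(keep)) < repressor_fraction,
                                    -1, 1),
                      stringsAsFactors = FALSE)
  pathway_graph(genes, edges)
}

# Planted-partition (stochastic block model) edge list for MCL tests.
planted_partition_edges <- function(block_sizes, p_within, p_between,
                                    seed) {
  set.seed(seed)
  genes <- sprintf("v%03d", seq_len(sum(block_sizes)))
  block <- rep(seq_along(block_sizes), block_sizes)
  n <- length(genes)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  p <- ifelse(block[idx[, 1]] == block[idx[, 2]], p_within, p_between)
  keep <- runif(nrow(idx)) < p
  list(edges = data.frame(from = genes[idx[keep, 1]],
                          to = genes[idx[keep, 2]], weight = 1,
                          stringsAsFactors = FALSE),
       genes = genes, block = block)
}

# Area under the ROC curve for scores of positives vs negatives.
auroc <- function(pos, neg) {
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

# A tiny zero-noise planted matrix used across tests.
tiny_planted <- function(n_genes = 100, frac_up = 0.2, frac_down = 0.3,
                         noise_sd = 0, seed = 42) {
  generate_dose_series(sim_config(n_genes = n_genes, frac_up = frac_up,
                                  frac_down = frac_down,
                                  effect_size = 1, noise_sd = noise_sd,
                                  seed = seed))
}
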