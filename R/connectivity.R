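# Local Connectivity-Map scoring engine: two-sided Kolmogorov-Smirnov tag
# enrichment of a query signature against rank-ordered reference instances,
# raw score combination with the same-sign zero rule, compendium-wide
# score scaling, and permutation p-values.

#' KS enrichment of a tag list against one ranked instance
#'
#' With `t` tags at ascending ranks `V(1) < ... < V(t)` inside a universe
#' of `n` genes ranked from most up-regulated (1) to most down-regulated
#' (n), computes `a = max_j (j/t - V(j)/n)` and `b = max_j (V(j)/n -
#' (j-1)/t)` and returns `a` if `a > b`, else `-b`.  Positive values mean
#' the tags crowd the top of the ranking.
#'
#' @param ranks Named integer vector giving each universe gene's rank
#'   (a complete permutation of `1..n`).
#' @param tags Gene identifiers to score; must all be present in `ranks`.
#' @return Enrichment score in `[-1, 1]`.
#' @export
ks_enrichment <- function(ranks, tags) {
  if (!length(tags)) stop("tag list is empty", call. = FALSE)
  missing <- setdiff(tags, names(ranks))
  if (length(missing)) {
    stop(sprintf("tags absent from the ranked universe: %s",
                 paste(head(missing, 10), collapse = ", ")), call. = FALSE)
  }
  ks_from_ranks(sort(unname(ranks[tags])), length(ranks))
}

# Core statistic on sorted tag ranks; shared with the permutation null.
ks_from_ranks <- function(v, n) {
  t <- length(v)
  j <- seq_len(t)
  a <- max(j / t - v / n)
  b <- max(v / n - (j - 1) / t)
  if (a > b) a else -b
}

#' Combine up- and down-tag enrichment into a raw connectivity score
#'
#' The score is 0 when both enrichments share a sign (or either is 0) —
#' the query then matches neither direction coherently — and
#' `ES_up - ES_down` otherwise.
#'
#' @param es_up,es_down Enrichment scores in `[-1, 1]`.
#' @return Raw connectivity score `s`.
#' @export
raw_connectivity <- function(es_up, es_down) {
  if (es_up == 0 || es_down == 0 || sign(es_up) == sign(es_down)) {
    return(0)
  }
  es_up - es_down
}

#' Scale raw connectivity scores to [-1, 1] across a compendium
#'
#' Positive scores are divided by the maximum positive score `p_max`,
#' negative scores by the maximum absolute negative score `q_max`; zeros
#' stay zero.  A branch with no members is skipped.
#'
#' @param raw Numeric vector of raw scores over all instances.
#' @return Scaled scores in `[-1, 1]`.
#' @export
scale_scores <- function(raw) {
  if (!length(raw)) stop("need at least one instance", call. = FALSE)
  out <- raw
  pos <- raw > 0
  neg <- raw < 0
  if (any(pos)) out[pos] <- raw[pos] / max(raw[pos])
  if (any(neg)) out[neg] <- raw[neg] / max(abs(raw[neg]))
  out
}

# Null raw connectivity scores for random disjoint tag sets of sizes
# (t_up, t_dn) drawn uniformly from a universe of size n.  The null does
# not depend on which particular permutation the instance carries, so one
# draw serves every instance of the same universe.
null_connectivity <- function(n, t_up, t_dn, n_perm) {
  vapply(seq_len(n_perm), function(b) {
    picks <- sample.int(n, t_up + t_dn)
    raw_connectivity(ks_from_ranks(sort(picks[seq_len(t_up)]), n),
                     ks_from_ranks(sort(picks[t_up + seq_len(t_dn)]), n))
  }, numeric(1))
}

#' Permutation p-value for an observed connectivity score
#'
#' Null scores come from `n_perm` random disjoint up/down tag sets drawn
#' uniformly from the universe; the two-sided p-value is
#' `(#\{|s_null| >= |s_obs|\} + 1) / (n_perm + 1)`.
#'
#' @param n Universe size.
#' @param t_up,t_down Tag-list sizes.
#' @param s_obs Observed raw connectivity score.
#' @param n_perm Number of null draws.
#' @param seed RNG seed.
#' @return p-value in `[1/(n_perm+1), 1]`.
#' @export
permutation_p <- function(n, t_up, t_down, s_obs, n_perm = 1000, seed = 1) {
  if (t_up + t_down > n) {
    stop("tag sizes exceed the universe", call. = FALSE)
  }
  nulls <- with_seed(seed, null_connectivity(n, t_up, t_down, n_perm))
  (sum(abs(nulls) >= abs(s_obs)) + 1) / (n_perm + 1)
}

#' Query a reference compendium with a signature
#'
#' Scores every instance with the two-sided KS tag enrichment, combines and
#' scales the scores, and attaches permutation p-values (one shared null
#' per query, since the null distribution depends only on the universe and
#' tag sizes).  Results are ordered by decreasing scaled score, then
#' p-value, then decreasing |raw|, then instance id.
#'
#' @param sig A [tag_signature()].
#' @param compendium A `reference_compendium`.
#' @param n_perm Number of permutation draws for the p-values.
#' @param seed RNG seed.
#' @return data.frame with columns instance, compound, cell_line, dose,
#'   es_up, es_down, raw, scaled, p.
#' @export
query_compendium <- function(sig, compendium, n_perm = 1000, seed = 1) {
  stopifnot(inherits(sig, "tag_signature"),
            inherits(compendium, "reference_compendium"))
  rm_ <- compendium$rank_matrix
  universe <- rownames(rm_)
  missing <- setdiff(c(sig$up_tags, sig$down_tags), universe)
  if (length(missing)) {
    stop(sprintf("signature tags absent from the compendium universe: %s",
                 paste(head(missing, 10), collapse = ", ")), call. = FALSE)
  }
  n <- length(universe)
  es_up <- apply(rm_, 2, function(r) {
    ks_from_ranks(sort(r[match(sig$up_tags, universe)]), n)
  })
  es_down <- apply(rm_, 2, function(r) {
    ks_from_ranks(sort(r[match(sig$down_tags, universe)]), n)
  })
  raw <- mapply(raw_connectivity, es_up, es_down)
  scaled <- scale_scores(raw)
  nulls <- with_seed(seed, null_connectivity(n, length(sig$up_tags),
                                             length(sig$down_tags), n_perm))
  p <- vapply(raw, function(s) {
    (sum(abs(nulls) >= abs(s)) + 1) / (n_perm + 1)
  }, numeric(1))
  out <- data.frame(compendium$instances,
                    es_up = es_up, es_down = es_down, raw = raw,
                    scaled = scaled, p = p,
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(-out$scaled, out$p, -abs(out$raw), out$instance_id), ,
      drop = FALSE]
}

#' Roll a per-instance result up to one row per compound
#'
#' Keeps each compound's best instance (highest scaled score, ties by
#' p-value then instance id).  This is a simple stand-in for the original
#' service's per-compound enrichment aggregation.
#'
#' @param result Output of [query_compendium()].
#' @return One-row-per-compound data.frame ordered like the input.
#' @export
compound_rollup <- function(result) {
  split_rows <- split(seq_len(nrow(result)), result$compound)
  best <- vapply(split_rows, function(i) {
    i[order(-result$scaled[i], result$p[i], result$instance_id[i])[1]]
  }, integer(1))
  out <- result[sort(best), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pearson correlation of scaled scores between two queries
#'
#' @param result_a,result_b Outputs of [query_compendium()].
#' @param instances Instance ids to compare over (default: all shared).
#' @return Pearson r (NA when either score vector is constant).
#' @export
compare_queries <- function(result_a, result_b,
                            instances = intersect(result_a$instance_id,
                                                  result_b$instance_id)) {
  if (length(instances) < 3L) {
    stop("need at least 3 shared instances", call. = FALSE)
  }
  a <- result_a$scaled[match(instances, result_a$instance_id)]
  b <- result_b$scaled[match(instances, result_b$instance_id)]
  if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
  cor(a, b)
}
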