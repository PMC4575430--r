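# Dose-dependent pattern mining in the style of short time-series profile
# analysis: genes are assigned to predefined integer-level model profiles by
# correlation, profile significance is assessed by permuting each gene's
# dose labels, and significant profiles pool into up- and down-regulated
# patterns from which fold-change tag signatures are drawn.

#' Enumerate integer-level model profiles
#'
#' All integer level sequences of length `n_doses` whose consecutive steps
#' are bounded by `c` in absolute value, starting from level 0 at the
#' vehicle; the all-zero profile is excluded.  The count is
#' `(2c+1)^n_doses - 1`.
#'
#' @param n_doses Number of doses beyond vehicle (>= 2 for pattern mining;
#'   1 is allowed for enumeration itself).
#' @param c Maximum absolute level change between consecutive doses
#'   (default 1; larger values enumerate a denser family whose
#'   near-proportional members compete for the same genes).
#' @return Integer matrix, one profile per row (rownames `p1..pm`), columns
#'   `d1..dn`; rows ordered lexicographically by level vector.
#' @export
enumerate_model_profiles <- function(n_doses, c = 1) {
  n_doses <- check_count(n_doses, "n_doses", min = 1L)
  c <- check_count(c, "c", min = 1L)
  steps <- do.call(expand.grid, rep(list(seq.int(-c, c)), n_doses))
  levels <- t(apply(as.matrix(steps), 1, cumsum))
  if (n_doses == 1L) levels <- t(levels)
  levels <- levels[rowSums(levels != 0) > 0, , drop = FALSE]
  levels <- levels[do.call(order, as.data.frame(levels)), , drop = FALSE]
  dimnames(levels) <- list(sprintf("p%d", seq_len(nrow(levels))),
                           paste0("d", seq_len(n_doses)))
  levels
}

# Correlation of each row of `expr` with each profile, both prefixed with
# the implicit vehicle level 0 so that constant-level profiles remain
# non-degenerate.  Returns the index of the best profile per gene (ties ->
# lowest profile id), NA for constant (all-zero-augmented) genes.
best_profile <- function(expr, profiles) {
  aug_e <- cbind(0, expr)
  aug_p <- cbind(0, profiles)
  keep <- apply(aug_e, 1, sd) > 0
  best <- rep(NA_integer_, nrow(expr))
  if (any(keep)) {
    cors <- cor(t(aug_e[keep, , drop = FALSE]), t(aug_p))
    # correlation is invariant under positive rescaling of a profile, so
    # proportional profiles tie exactly; round away float jitter so the
    # tie breaks deterministically to the lowest profile id
    best[keep] <- max.col(round(cors, 10), ties.method = "first")
  }
  names(best) <- rownames(expr)
  best
}

#' Assign genes to their best-correlated model profile
#'
#' Each non-constant gene is assigned to the profile maximizing the Pearson
#' correlation between its dose vector and the profile's level vector (both
#' augmented with the implicit vehicle 0); constant genes are unassigned;
#' ties break to the lowest profile id.
#'
#' @param expr Genes x doses log2-ratio matrix, columns in increasing dose
#'   order.
#' @param profiles Profile matrix from [enumerate_model_profiles()].
#' @return Named integer vector of profile row indices (NA = unassigned).
#' @export
assign_genes <- function(expr, profiles) {
  stopifnot(ncol(expr) == ncol(profiles))
  best_profile(as.matrix(expr), profiles)
}

# Permute each row's entries independently.  For small dose counts all d!
# permutations are tabulated and one is drawn per row, which vectorizes the
# inner loop of the permutation FDR.
shuffle_rows <- function(mat) {
  d <- ncol(mat)
  n <- nrow(mat)
  perms <- all_permutations(d)
  pick <- perms[sample.int(nrow(perms), n, replace = TRUE), , drop = FALSE]
  out <- matrix(mat[cbind(rep(seq_len(n), d), as.vector(pick))], n, d)
  rownames(out) <- rownames(mat)
  out
}

all_permutations <- function(d) {
  if (d == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(d - 1L)
  do.call(rbind, lapply(seq_len(d), function(k) {
    cbind(k, ifelse(sub >= k, sub + 1L, sub))
  }))
}

#' Permutation significance for model-profile assignment
#'
#' For each of `n_perm` permutations, every gene's dose-vector entries are
#' independently shuffled and the profile assignment recomputed.  The
#' expected count E per profile is the mean permuted count.  Two statistics
#' are reported per profile: the naive enrichment ratio `min(1, E / O)`
#' (`eo_ratio`; NA when O = 0), and the profile significance used for
#' calling, the binomial tail `P(X >= O)` with `X ~ Binomial(n_genes, E /
#' n_genes)`, Benjamini-Hochberg adjusted across profiles (`fdr`).  The
#' tail test is used for calling because with `d` doses the per-gene label
#' permutation reproduces the original assignment with probability `1/d!`,
#' so the raw E/O ratio can never drop below that floor regardless of
#' signal strength.
#'
#' @param expr Genes x doses log2-ratio matrix.
#' @param profiles Profile matrix from [enumerate_model_profiles()].
#' @param n_perm Number of permutations (default 1000).
#' @param seed RNG seed.
#' @param fdr_threshold Significance threshold on the adjusted tail
#'   probability (default 0.001).
#' @return A `pattern_result`: list with `profiles`, `assignment` (named
#'   profile index per gene), and a `table` data.frame (profile,
#'   final_level, observed, expected, eo_ratio, p, fdr, significant).
#' @export
profile_significance <- function(expr, profiles, n_perm = 1000, seed = 1,
                                 fdr_threshold = 0.001) {
  expr <- as.matrix(expr)
  n_perm <- check_count(n_perm, "n_perm", min = 1L)
  m <- nrow(profiles)
  n <- nrow(expr)
  assignment <- assign_genes(expr, profiles)
  observed <- tabulate(assignment, nbins = m)
  perm_counts <- matrix(0, n_perm, m)
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      shuffled <- shuffle_rows(expr)
      perm_counts[b, ] <- tabulate(best_profile(shuffled, profiles),
                                   nbins = m)
    }
  })
  expected <- colMeans(perm_counts)
  eo_ratio <- ifelse(observed > 0, pmin(1, expected / observed), NA_real_)
  p <- stats::pbinom(observed - 1L, n, pmin(expected / n, 1),
                     lower.tail = FALSE)
  fdr <- p.adjust(p, method = "BH")
  tab <- data.frame(
    profile = rownames(profiles),
    final_level = profiles[, ncol(profiles)],
    observed = observed,
    expected = expected,
    eo_ratio = eo_ratio,
    p = p,
    fdr = fdr,
    significant = observed > 0 & fdr < fdr_threshold,
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(profiles = profiles, assignment = assignment,
                 table = tab, n_perm = n_perm,
                 fdr_threshold = fdr_threshold),
            class = "pattern_result")
}

#' Pool significant profiles into up- and down-regulated patterns
#'
#' Significant profiles with a positive final level pool into the up
#' pattern, negative final level into the down pattern; a significant
#' profile ending at level 0 is excluded with a warning.
#'
#' @param result A `pattern_result` from [profile_significance()].
#' @return List with `up` and `down` gene-identifier vectors.
#' @export
merge_patterns <- function(result) {
  stopifnot(inherits(result, "pattern_result"))
  tab <- result$table
  sig <- which(tab$significant)
  flat <- sig[tab$final_level[sig] == 0]
  if (length(flat)) {
    warning(sprintf("excluding %d significant profile(s) with final level 0",
                    length(flat)))
  }
  genes_of <- function(idx) {
    sort(names(result$assignment)[result$assignment %in% idx])
  }
  list(up = genes_of(sig[tab$final_level[sig] > 0]),
       down = genes_of(sig[tab$final_level[sig] < 0]))
}

#' Select fold-change tag signature at the highest dose
#'
#' Up-tags are the genes with linear ratio strictly above `fold_up` at the
#' highest dose; down-tags strictly below `fold_down`.  Tags are ordered by
#' decreasing absolute log-ratio.
#'
#' @param expr Genes x doses log2-ratio matrix, columns in increasing dose
#'   order.
#' @param fold_up Linear-ratio threshold for up-tags (default 4).
#' @param fold_down Linear-ratio threshold for down-tags (default 0.25).
#' @return A `signature`: list with `up_tags`, `down_tags`, `fold_up`,
#'   `fold_down`.
#' @export
select_tags <- function(expr, fold_up = 4, fold_down = 0.25) {
  if (!(fold_up > 1 && fold_down < 1 && fold_down > 0)) {
    stop("need fold_up > 1 > fold_down > 0", call. = FALSE)
  }
  expr <- as.matrix(expr)
  top <- expr[, ncol(expr)]
  ratio <- 2^top
  up <- names(sort(top[ratio > fold_up], decreasing = TRUE))
  down <- names(sort(top[ratio < fold_down]))
  if (!length(up) || !length(down)) {
    stop(paste("no genes pass the tag thresholds on one side;",
               "relax fold_up/fold_down"), call. = FALSE)
  }
  tag_signature(up, down, fold_up = fold_up, fold_down = fold_down)
}

#' Query signature of up- and down-tags
#' @param up_tags,down_tags Disjoint ordered gene lists, both non-empty.
#' @param fold_up,fold_down Thresholds used to derive the tags (metadata).
#' @export
tag_signature <- function(up_tags, down_tags, fold_up = NA, fold_down = NA) {
  if (!length(up_tags) || !length(down_tags)) {
    stop("both tag lists must be non-empty", call. = FALSE)
  }
  if (length(intersect(up_tags, down_tags))) {
    stop("up- and down-tags must be disjoint", call. = FALSE)
  }
  structure(list(up_tags = up_tags, down_tags = down_tags,
                 fold_up = fold_up, fold_down = fold_down),
            class = "tag_signature")
}

#' Overlap of two gene sets as a count and percentage of the first
#'
#' @param set_a,set_b Gene-identifier vectors.
#' @return List with `overlap` (|A intersect B|) and `percent`
#'   (100 * overlap / |A|, rounded to 1 decimal; NA when A is empty).
#' @export
pattern_overlap <- function(set_a, set_b) {
  ov <- length(intersect(set_a, set_b))
  pct <- if (length(set_a) == 0) NA_real_ else
    round(100 * ov / length(set_a), 1)
  list(overlap = ov, percent = pct)
}
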