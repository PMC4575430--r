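# Interaction-graph construction, Markov clustering, and module filtering
# by size and expression coherence.

test_that("graph construction induces, deduplicates and validates", {
  edges <- data.frame(from = c("a", "b", "a", "a"),
                      to = c("b", "c", "b", "a"),
                      weight = c(1, 1, 5, 1), stringsAsFactors = FALSE)
  g <- build_graph(edges, c("a", "b"))
  expect_equal(igraph::ecount(g), 1)
  expect_equal(igraph::E(g)$weight, 5)  # duplicates keep max weight
  expect_error(build_graph(edges, c("x", "y")), "no interactions")
})

test_that("MCL recovers disconnected components exactly", {
  tri <- function(v) data.frame(from = v[c(1, 2, 3)], to = v[c(2, 3, 1)],
                                weight = 1, stringsAsFactors = FALSE)
  edges <- rbind(tri(c("a1", "a2", "a3")), tri(c("b1", "b2", "b3")))
  g <- build_graph(edges, unique(c(edges$from, edges$to)))
  part <- mcl(g, inflation = 5)
  expect_equal(part$n_clusters, 2)
  m <- part$membership
  expect_length(unique(m[c("a1", "a2", "a3")]), 1)
  expect_length(unique(m[c("b1", "b2", "b3")]), 1)
  expect_false(m[["a1"]] == m[["b1"]])
  # single triangle collapses to one cluster
  g1 <- build_graph(tri(c("x", "y", "z")), c("x", "y", "z"))
  expect_equal(mcl(g1, inflation = 5)$n_clusters, 1)
})

test_that("two cliques joined by a bridge split at the bridge", {
  clique <- function(v) {
    idx <- t(utils::combn(length(v), 2))
    data.frame(from = v[idx[, 1]], to = v[idx[, 2]], weight = 1,
               stringsAsFactors = FALSE)
  }
  a <- sprintf("a%d", 1:5); b <- sprintf("b%d", 1:5)
  edges <- rbind(clique(a), clique(b),
                 data.frame(from = "a1", to = "b1", weight = 1,
                            stringsAsFactors = FALSE))
  g <- build_graph(edges, c(a, b))
  for (prune in c(1e-5, 1e-4, 1e-3)) {
    part <- mcl(g, inflation = 5, prune_threshold = prune)
    expect_equal(part$n_clusters, 2)
    expect_length(unique(part$membership[a]), 1)
    expect_length(unique(part$membership[b]), 1)
  }
})

test_that("MCL output is a partition that never crosses components", {
  pp <- planted_partition_edges(c(8, 8, 8), p_within = 0.9,
                                p_between = 0, seed = 33)
  g <- build_graph(pp$edges, pp$genes)
  part <- mcl(g, inflation = 2)
  present <- igraph::V(g)$name
  expect_setequal(names(part$membership), present)
  comp <- igraph::components(g)$membership[names(part$membership)]
  # cluster labels refine the component labels
  tab <- table(part$membership, comp)
  expect_true(all(rowSums(tab > 0) == 1))
})

test_that("planted 3x10 partition is recovered at moderate inflation", {
  pp <- planted_partition_edges(c(10, 10, 10), p_within = 0.8,
                                p_between = 0.05, seed = 34)
  g <- build_graph(pp$edges, pp$genes)
  part <- mcl(g, inflation = 2)
  membership <- part$membership[pp$genes]
  expect_equal(part$n_clusters, 3)
  for (b in 1:3) {
    expect_length(unique(membership[pp$block == b]), 1)
  }
  # high inflation trades completeness for purity: the finer clusters
  # refine the planted blocks without ever straddling them
  fine <- mcl(g, inflation = 5)$membership[pp$genes]
  tab <- table(fine, pp$block)
  expect_true(all(rowSums(tab > 0) == 1))
})

test_that("cluster count trends upward with inflation", {
  counts <- vapply(c(1.5, 2, 5), function(infl) {
    total <- 0
    for (s in 1:3) {
      pp <- planted_partition_edges(c(9, 9, 9), p_within = 0.7,
                                    p_between = 0.15, seed = 60 + s)
      g <- build_graph(pp$edges, pp$genes)
      total <- total + mcl(g, inflation = infl)$n_clusters
    }
    total
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("module filter applies the size and coherence boundaries", {
  sim <- tiny_planted(n_genes = 60, frac_up = 0.5, frac_down = 0.5)
  up <- sim$truth$up_genes
  dn <- sim$truth$down_genes
  membership <- setNames(c(rep(1L, 7), rep(2L, 6), rep(3L, 5), rep(3L, 5)),
                         c(up[1:7], up[8:13], up[14:18], dn[1:5]))
  mods <- filter_modules(membership, sim$expr)
  # 7 perfect genes retained (size boundary inclusive), 6 dropped,
  # mixed-direction cluster dropped on coherence
  expect_length(mods$members, 1)
  expect_setequal(mods$members[["0"]], up[1:7])
  expect_equal(mods$summary$mean_corr, 1)
  # mixed cluster really fails the 0.8 bar
  mixed <- c(up[14:18], dn[1:5])
  cc <- cor(t(sim$expr[mixed, ]))
  expect_lt(mean(cc[upper.tri(cc)]), 0.8)
})

test_that("surviving modules are renumbered by decreasing size", {
  sim <- tiny_planted(n_genes = 100, frac_up = 1, frac_down = 0,
                      noise_sd = 0.01, seed = 35)
  genes <- sim$truth$up_genes
  membership <- setNames(c(rep(1L, 8), rep(2L, 12)), genes[1:20])
  mods <- filter_modules(membership, sim$expr)
  expect_equal(names(mods$members), c("0", "1"))
  expect_equal(lengths(mods$members), c(`0` = 12, `1` = 8))
})
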