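# KS tag enrichment, score combination and scaling, permutation p-values,
# compendium queries and query comparison.

ranks_of <- function(n) setNames(seq_len(n), sprintf("g%02d", seq_len(n)))

test_that("KS enrichment reproduces the worked two-max cases", {
  r <- ranks_of(10)
  expect_equal(ks_enrichment(r, c("g01", "g02")), 0.8)
  expect_equal(ks_enrichment(r, c("g09", "g10")), -0.9)
  expect_error(ks_enrichment(r, c("g01", "nope")), "nope")
})

test_that("KS enrichment equals the exhaustive step-function oracle", {
  for (n in 4:8) {
    r <- ranks_of(n)
    for (t in 1:min(4, n)) {
      placements <- utils::combn(n, t)
      for (j in seq_len(ncol(placements))) {
        v <- placements[, j]
        es <- ks_enrichment(r, names(r)[v])
        expect_equal(es, ks_oracle(v, n))
        expect_gte(es, -1)
        expect_lte(es, 1)
      }
    }
  }
})

test_that("reversing a ranking negates the enrichment up to the 1/n grid shift", {
  # exact discrete relation: a(rev) = b(fwd) - 1/n and b(rev) = a(fwd) + 1/n,
  # so away from the a/b tie branch the reversed ES is the negated ES
  # shifted by exactly one rank-grid step
  set.seed(3)
  n <- 40
  for (i in 1:25) {
    v <- sort(sample(n, 5))
    t <- length(v); j <- seq_len(t)
    a <- max(j / t - v / n); b <- max(v / n - (j - 1) / t)
    if (abs(a - b) > 2 / n + 1e-9) {  # both branches decisive after shift
      r <- ranks_of(n)
      tags <- names(r)[v]
      rev_r <- setNames(n + 1 - r, names(r))
      diff_ <- ks_enrichment(rev_r, tags) + ks_enrichment(r, tags)
      expect_equal(abs(diff_), 1 / n)
    }
  }
})

test_that("raw score combination applies the same-sign zero rule", {
  expect_equal(raw_connectivity(0.8, -0.7), 1.5)
  expect_equal(raw_connectivity(0.8, 0.3), 0)
  expect_equal(raw_connectivity(-0.6, 0.4), -1.0)
  expect_equal(raw_connectivity(0, -0.5), 0)
})

test_that("score scaling divides by the positive and negative extrema", {
  expect_equal(scale_scores(c(1.5, 0.75, -0.5)), c(1, 0.5, -1))
  expect_equal(scale_scores(c(0, 0)), c(0, 0))
  expect_equal(scale_scores(0.42), 1)
})

test_that("permutation p-values obey the add-one estimator bounds", {
  expect_equal(permutation_p(50, 3, 3, s_obs = 0, n_perm = 99, seed = 1), 1)
  p <- permutation_p(100, 5, 5, s_obs = 1.2, n_perm = 99, seed = 2)
  expect_gte(p, 1 / 100)
  expect_lte(p, 1)
})

test_that("a perfect mimic attains the minimal permutation p-value", {
  # universe of 1000 with tags at the exact extremes
  n <- 1000
  r <- setNames(seq_len(n), sprintf("g%04d", seq_len(n)))
  es_up <- ks_enrichment(r, names(r)[1:10])
  es_dn <- ks_enrichment(r, names(r)[(n - 9):n])
  s <- raw_connectivity(es_up, es_dn)
  expect_gt(s, 1.9)
  expect_equal(permutation_p(n, 10, 10, s, n_perm = 999, seed = 5),
               1 / 1000)
})

test_that("a signature from an instance's own extremes retrieves it first", {
  sim <- tiny_planted(noise_sd = 0.2)
  comp <- generate_reference_compendium(sim$truth, 12, 3,
                                        rank_noise_sd = 0.5, seed = 6)
  target <- "inst007"
  ranks <- comp$rank_matrix[, target]
  u <- names(sort(ranks))[1:8]
  d <- names(sort(ranks, decreasing = TRUE))[1:8]
  res <- query_compendium(tag_signature(u, d), comp, n_perm = 200, seed = 7)
  expect_equal(res$instance_id[1], target)
  expect_equal(res$scaled[1], 1.0)
})

test_that("zero-noise compendium separates mimics from decoys perfectly", {
  sim <- tiny_planted()
  comp <- generate_reference_compendium(sim$truth, 30, 8,
                                        rank_noise_sd = 0, seed = 8)
  sig <- tag_signature(sim$truth$up_genes, sim$truth$down_genes)
  res <- query_compendium(sig, comp, n_perm = 100, seed = 9)
  is_mimic <- res$instance_id %in% comp$mimic_instances
  # every mimic above every decoy
  expect_true(max(which(is_mimic)) < min(which(!is_mimic)))
  expect_equal(auroc(res$scaled[is_mimic], res$scaled[!is_mimic]), 1.0)
})

test_that("anti-mimics land at the bottom with the extreme negative score", {
  sim <- tiny_planted()
  comp <- generate_reference_compendium(sim$truth, 20, 6,
                                        inversion_fraction = 0.5,
                                        rank_noise_sd = 0, seed = 10)
  sig <- tag_signature(sim$truth$up_genes, sim$truth$down_genes)
  res <- query_compendium(sig, comp, n_perm = 100, seed = 11)
  tail_ids <- utils::tail(res$instance_id, length(comp$anti_instances))
  expect_setequal(tail_ids, comp$anti_instances)
  expect_equal(min(res$scaled), -1)
})

test_that("retrieval degrades monotonically with mimic rank noise", {
  sim <- tiny_planted(n_genes = 200, noise_sd = 0)
  aucs <- vapply(c(0, 3, 10), function(ns) {
    comp <- generate_reference_compendium(sim$truth, 40, 10,
                                          rank_noise_sd = ns, seed = 12)
    sig <- tag_signature(sim$truth$up_genes, sim$truth$down_genes)
    res <- query_compendium(sig, comp, n_perm = 50, seed = 13)
    is_mimic <- res$instance_id %in% comp$mimic_instances
    auroc(res$scaled[is_mimic], res$scaled[!is_mimic])
  }, numeric(1))
  expect_equal(aucs[1], 1.0)
  expect_true(all(diff(aucs) <= 0))
  expect_gt(aucs[1], aucs[3])
})

test_that("decoy-only compendium p-values are not anti-conservative", {
  sim <- tiny_planted(n_genes = 300)
  comp <- generate_reference_compendium(sim$truth, 60, 0, seed = 14)
  sig <- tag_signature(sim$truth$up_genes[1:15], sim$truth$down_genes[1:15])
  res <- query_compendium(sig, comp, n_perm = 400, seed = 15)
  ks <- suppressWarnings(
    stats::ks.test(res$p, "punif", alternative = "greater"))
  expect_gt(ks$p.value, 0.01)
  expect_lte(mean(res$p < 0.05), 0.15)
})

test_that("query comparison recovers the closed-form Pearson correlation", {
  mk <- function(scaled) data.frame(instance_id = c("i1", "i2", "i3"),
                                    scaled = scaled,
                                    stringsAsFactors = FALSE)
  expect_equal(compare_queries(mk(c(1, 0.5, -1)), mk(c(1, 0.5, -1))), 1.0)
  expect_equal(compare_queries(mk(c(1, 0.5, -1)), mk(-c(1, 0.5, -1))), -1.0)
  a <- c(1, 0.5, -1); b <- c(0.9, 0.4, -0.8)
  r_closed <- (sum(a * b) - 3 * mean(a) * mean(b)) /
    sqrt((sum(a^2) - 3 * mean(a)^2) * (sum(b^2) - 3 * mean(b)^2))
  expect_equal(compare_queries(mk(a), mk(b)), r_closed)
  expect_true(is.na(compare_queries(mk(c(1, 1, 1)), mk(b))))
  expect_error(compare_queries(mk(a)[1:2, ], mk(b)[1:2, ]), "at least 3")
})

test_that("compound rollup keeps each compound's best instance", {
  res <- data.frame(instance_id = c("i1", "i2", "i3", "i4"),
                    compound = c("A", "A", "B", "B"),
                    scaled = c(1, 0.8, -0.2, 0.5),
                    p = c(0.01, 0.02, 0.5, 0.1),
                    stringsAsFactors = FALSE)
  roll <- compound_rollup(res)
  expect_equal(nrow(roll), 2)
  expect_setequal(roll$instance_id, c("i1", "i4"))
})
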