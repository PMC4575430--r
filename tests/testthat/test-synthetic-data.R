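# Generators: planted structure, determinism, and the partition invariant.

test_that("zero-noise dose series plants exact block counts and monotone rows", {
  sim <- tiny_planted()
  expr <- sim$expr
  truth <- sim$truth
  expect_equal(length(truth$up_genes), 20)
  expect_equal(length(truth$down_genes), 30)
  expect_equal(length(truth$null_genes), 50)
  # partition of the universe
  expect_setequal(c(truth$up_genes, truth$down_genes, truth$null_genes),
                  rownames(expr))
  expect_equal(anyDuplicated(c(truth$up_genes, truth$down_genes,
                               truth$null_genes)), 0)
  # monotone planting at zero noise
  up <- expr[truth$up_genes, , drop = FALSE]
  down <- expr[truth$down_genes, , drop = FALSE]
  expect_true(all(up[, 2] > up[, 1] & up[, 3] > up[, 2]))
  expect_true(all(down[, 2] < down[, 1] & down[, 3] < down[, 2]))
  expect_true(all(expr[truth$null_genes, ] == 0))
  # expected values are effect_size * dose index
  expect_equal(unname(up[1, ]), c(1, 2, 3))
})

test_that("identical config and seed reproduce outputs bit for bit", {
  cfg <- sim_config(n_genes = 150, noise_sd = 0.2, seed = 7)
  s1 <- generate_dose_series(cfg)
  s2 <- generate_dose_series(cfg)
  expect_identical(s1, s2)
  c1 <- generate_reference_compendium(s1$truth, 12, 4, seed = 9)
  c2 <- generate_reference_compendium(s1$truth, 12, 4, seed = 9)
  expect_identical(c1, c2)
  g1 <- generate_gene_sets(s1$truth, 8, seed = 5)
  g2 <- generate_gene_sets(s1$truth, 8, seed = 5)
  expect_identical(g1, g2)
})

test_that("up-block sample mean at the top dose is near its planted value", {
  sim <- generate_dose_series(sim_config(n_genes = 1000, effect_size = 1,
                                         noise_sd = 0.1, seed = 1))
  top <- sim$expr[sim$truth$up_genes, 3]
  n_up <- length(top)
  expect_lt(abs(mean(top) - 3), 3 / sqrt(n_up))
})

test_that("invalid simulation configurations are rejected", {
  expect_error(sim_config(frac_up = 0.7, frac_down = 0.5), "exceed 1")
  expect_error(sim_config(n_doses = 1), "n_doses")
  expect_error(sim_config(noise_sd = -1), "noise_sd")
  expect_error(sim_config(n_genes = 0), "n_genes")
})

test_that("compendium instances are complete permutations of the universe", {
  sim <- tiny_planted()
  comp <- generate_reference_compendium(sim$truth, 15, 5,
                                        inversion_fraction = 0.4,
                                        rank_noise_sd = 0.3, seed = 3)
  n <- length(comp$universe)
  for (i in seq_len(ncol(comp$rank_matrix))) {
    expect_setequal(comp$rank_matrix[, i], seq_len(n))
  }
  expect_length(comp$mimic_instances, 3)  # 5 mimics, 40% inverted
  expect_length(comp$anti_instances, 2)
})

test_that("perfect mimics rank planted up-genes in the first |up| positions", {
  sim <- tiny_planted()
  comp <- generate_reference_compendium(sim$truth, 10, 2,
                                        rank_noise_sd = 0, seed = 1)
  ranks <- comp$rank_matrix[, comp$mimic_instances[1]]
  expect_setequal(ranks[sim$truth$up_genes],
                  seq_along(sim$truth$up_genes))
  expect_setequal(ranks[sim$truth$down_genes],
                  length(comp$universe) + 1 -
                    seq_along(sim$truth$down_genes))
  # anti-mimics invert the placement
  comp_anti <- generate_reference_compendium(sim$truth, 4, 2,
                                             inversion_fraction = 1,
                                             rank_noise_sd = 0, seed = 2)
  anti_ranks <- comp_anti$rank_matrix[, comp_anti$anti_instances[1]]
  expect_setequal(anti_ranks[sim$truth$up_genes],
                  length(comp_anti$universe) + 1 -
                    seq_along(sim$truth$up_genes))
})

test_that("gene-set generator respects purity, counts and edge cases", {
  sim <- tiny_planted()
  coll <- generate_gene_sets(sim$truth, n_sets = 10, set_size = c(8, 15),
                             n_enriched_up = 2, n_enriched_down = 2,
                             seed = 4)
  expect_length(coll$sets, 10)
  up_sets <- grep("^up_enriched", names(coll$sets))
  for (i in up_sets) {
    frac <- mean(coll$sets[[i]] %in% sim$truth$up_genes)
    expect_gte(frac, 0.8)
  }
  empty <- generate_gene_sets(sim$truth, 0, n_enriched_up = 0,
                              n_enriched_down = 0, seed = 1)
  expect_length(empty$sets, 0)
  expect_error(generate_gene_sets(sim$truth, 1, n_enriched_up = 1,
                                  n_enriched_down = 1, seed = 1),
               "exceed")
})

test_that("topology generator honors sign and density settings", {
  genes <- sprintf("g%02d", 1:8)
  g0 <- generate_pathway_topology(genes, edge_density = 0.5,
                                  repressor_fraction = 0, seed = 2)
  expect_true(all(g0$edges$sign == 1))
  g_none <- generate_pathway_topology(genes, edge_density = 0, seed = 2)
  expect_equal(nrow(g_none$edges), 0)
  pert <- perturbation(g_none, setNames(c(1, -1), genes[1:2]))
  expect_true(all(pert$acc == 0))
  expect_equal(pert$ta, 0)
  g_full <- generate_pathway_topology(c("a", "b", "c"), edge_density = 1,
                                      repressor_fraction = 0.5, seed = 3)
  expect_equal(nrow(g_full$edges), 6)
})

test_that("raw-intensity emitter feeds preprocessing back to the planted signal", {
  # quantile normalization presumes most genes unchanged, so the planted
  # fraction is kept small here as on a real array
  sim <- generate_dose_series(sim_config(n_genes = 400, frac_up = 0.05,
                                         frac_down = 0.05, noise_sd = 0.3,
                                         seed = 11))
  raw <- generate_raw_intensities(sim$expr, frac_low = 0.1, seed = 12)
  expect_length(raw$probe_id, 800)
  res <- preprocess_raw(raw)
  expect_lt(res$provenance$n_probes_kept, res$provenance$n_probes_in)
  common <- intersect(rownames(res$expr), rownames(sim$expr))
  r <- cor(as.vector(res$expr[common, ]), as.vector(sim$expr[common, ]))
  expect_gt(r, 0.6)
  # the reciprocal structure survives with the correct signs (attenuated
  # and compressed at the top dose by the normalization)
  up <- intersect(rownames(res$expr), sim$truth$up_genes)
  dn <- intersect(rownames(res$expr), sim$truth$down_genes)
  expect_true(all(colMeans(res$expr[up, ]) > 1))
  expect_true(all(colMeans(res$expr[dn, ]) < -1))
  expect_gt(mean(res$expr[up, 3]), mean(res$expr[up, 1]))
  expect_lt(mean(res$expr[dn, 3]), mean(res$expr[dn, 1]))
})
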