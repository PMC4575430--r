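# End-to-end orchestration: simulate every input, then run the analysis
# stages in the study's order -- patterns -> tags -> connectivity ->
# enrichment -> activity -> impact analysis -> network modules -- writing
# each stage's TSV output and a JSON provenance manifest into a run
# directory.

#' Pipeline configuration
#'
#' Collects the stage parameters (each defaulting to its module default)
#' and the global seed from which every stochastic stage derives its own
#' sub-seed.
#'
#' @param n_genes,n_doses,frac_up,frac_down,effect_size,noise_sd Simulation
#'   design, see [sim_config()].
#' @param n_instances,n_mimics,inversion_fraction,rank_noise_sd Compendium
#'   design, see [generate_reference_compendium()].
#' @param n_sets,set_size,n_enriched_up,n_enriched_down Gene-set design,
#'   see [generate_gene_sets()].
#' @param n_topologies,topology_size,edge_density,repressor_fraction
#'   Pathway-topology design, see [generate_pathway_topology()].
#' @param pattern_fdr Profile significance threshold.
#' @param fold_up,fold_down Tag thresholds (linear ratios).
#' @param n_perm Permutations for pattern and activity significance and
#'   the connectivity p-values.
#' @param n_boot Bootstrap replicates for the impact analysis.
#' @param inflation,min_module_size,min_module_corr Network-module stage.
#' @param seed Global RNG seed (mandatory for reproducibility).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_genes = 1000, n_doses = 3, frac_up = 0.2,
                            frac_down = 0.3, effect_size = 1,
                            noise_sd = 0.1,
                            n_instances = 50, n_mimics = 10,
                            inversion_fraction = 0.2, rank_noise_sd = 0.25,
                            n_sets = 30, set_size = c(10, 30),
                            n_enriched_up = 3, n_enriched_down = 3,
                            n_topologies = 10, topology_size = 20,
                            edge_density = 0.15, repressor_fraction = 0.3,
                            pattern_fdr = 0.001, fold_up = 4,
                            fold_down = 0.25, n_perm = 1000,
                            n_boot = 3000, inflation = 5,
                            min_module_size = 7, min_module_corr = 0.8,
                            seed = 1) {
  cfg <- as.list(environment())
  structure(cfg, class = "pipeline_config")
}

#' Run the full pipeline into a directory
#'
#' Simulates the planted inputs, executes the seven analysis stages in
#' order, writes every stage output as TSV under `out_dir`, and records a
#' JSON manifest with the parameters, the seed, md5 checksums of the
#' simulated inputs and per-stage record counts.  Rerunning with an
#' identical configuration reproduces identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Run directory (created; must not already contain a
#'   manifest, outputs are write-once).
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  if (file.exists(file.path(out_dir, "manifest.json"))) {
    stop("run directory already contains a manifest; refusing to overwrite",
         call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- derive_seeds(config$seed, 9)

  ## inputs: simulate everything with planted truth
  sim <- generate_dose_series(sim_config(
    n_genes = config$n_genes, n_doses = config$n_doses,
    frac_up = config$frac_up, frac_down = config$frac_down,
    effect_size = config$effect_size, noise_sd = config$noise_sd,
    seed = seeds[1]))
  expr <- sim$expr
  truth <- sim$truth
  compendium <- generate_reference_compendium(
    truth, n_instances = config$n_instances, n_mimics = config$n_mimics,
    inversion_fraction = config$inversion_fraction,
    rank_noise_sd = config$rank_noise_sd, seed = seeds[2])
  collection <- generate_gene_sets(
    truth, n_sets = config$n_sets, set_size = config$set_size,
    n_enriched_up = config$n_enriched_up,
    n_enriched_down = config$n_enriched_down, seed = seeds[3])
  topo_seeds <- derive_seeds(seeds[4], config$n_topologies)
  topologies <- lapply(seq_len(config$n_topologies), function(i) {
    if (i == 1) {
      # one topology planted as a coherent activation cascade on the up
      # block, so both the activity and the perturbation evidence are real
      generate_pathway_topology(head(truth$up_genes, config$topology_size),
                                edge_density = config$edge_density,
                                repressor_fraction = 0,
                                seed = topo_seeds[i])
    } else {
      members <- with_seed(topo_seeds[i],
                           sample(truth_universe(truth),
                                  config$topology_size))
      generate_pathway_topology(members,
                                edge_density = config$edge_density,
                                repressor_fraction = config$repressor_fraction,
                                seed = topo_seeds[i])
    }
  })
  names(topologies) <- sprintf("pw%02d", seq_along(topologies))
  network <- generate_interaction_network(truth, seed = seeds[5])

  write_expression_tsv(expr, file.path(out_dir, "expression.tsv"))
  write_compendium_tsv(compendium, file.path(out_dir, "compendium_ranks.tsv"),
                       file.path(out_dir, "compendium_instances.tsv"))
  write_gmt(collection, file.path(out_dir, "gene_sets.gmt"))
  for (nm in names(topologies)) {
    write_edge_tsv(topologies[[nm]],
                   file.path(out_dir, sprintf("topology_%s.tsv", nm)))
  }
  write.table(network, file.path(out_dir, "network_edges.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  stages <- list()

  ## 1. dose patterns
  profiles <- enumerate_model_profiles(config$n_doses)
  patt <- profile_significance(expr, profiles, n_perm = config$n_perm,
                               seed = seeds[6],
                               fdr_threshold = config$pattern_fdr)
  merged <- merge_patterns(patt)
  write.table(patt$table, file.path(out_dir, "patterns.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeLines(c(">UP", merged$up, ">DOWN", merged$down),
             file.path(out_dir, "pattern_genes.txt"))
  stages$patterns <- list(n_profiles = nrow(profiles),
                          n_significant = sum(patt$table$significant),
                          n_up = length(merged$up),
                          n_down = length(merged$down))

  ## 2. tag signature
  sig <- select_tags(expr, fold_up = config$fold_up,
                     fold_down = config$fold_down)
  write_tagfile(sig, file.path(out_dir, "signature_tags.txt"))
  stages$tags <- list(n_up_tags = length(sig$up_tags),
                      n_down_tags = length(sig$down_tags))

  ## 3. connectivity query
  cmap <- query_compendium(sig, compendium, n_perm = config$n_perm,
                           seed = seeds[7])
  write.table(cmap, file.path(out_dir, "connectivity.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  stages$cmap <- list(n_instances = nrow(cmap),
                      top_instance = cmap$instance_id[1])

  ## 4. enrichment of both patterns
  enr_up <- enrich(merged$up, collection)
  enr_down <- enrich(merged$down, collection)
  write.table(enr_up, file.path(out_dir, "enrichment_up.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(enr_down, file.path(out_dir, "enrichment_down.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  stages$enrich <- list(top_up_set = enr_up$name[1],
                        top_down_set = enr_down$name[1])

  ## 5. pathway activity over the topology gene sets
  pw_sets <- lapply(topologies, `[[`, "genes")
  pw_roles <- lapply(topologies, repressor_roles)
  act <- activity_fdr(expr, pw_sets, roles = pw_roles,
                      n_perm = config$n_perm, seed = seeds[8])
  write.table(data.frame(pathway = rownames(act$activity), act$activity,
                         check.names = FALSE),
              file.path(out_dir, "activity.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(act$table, file.path(out_dir, "activity_fdr.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  stages$activity <- list(n_pathways = nrow(act$table),
                          n_significant = sum(act$table$fdr < 0.01))

  ## 6. pathway impact analysis on the merged patterns
  de_genes <- c(merged$up, merged$down)
  de <- setNames(expr[de_genes, ncol(expr)], de_genes)
  spia_tab <- run_spia(de, universe = rownames(expr),
                       topologies = topologies, n_boot = config$n_boot,
                       seed = seeds[9])
  write.table(spia_tab, file.path(out_dir, "spia.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  stages$spia <- list(n_pathways = nrow(spia_tab),
                      n_sig01 = sum(spia_tab$sig01),
                      top_pathway = spia_tab$pathway[1])

  ## 7. network modules on the pattern genes
  graph <- build_graph(network, de_genes)
  part <- mcl(graph, inflation = config$inflation)
  modules <- filter_modules(part, expr, min_size = config$min_module_size,
                            min_corr = config$min_module_corr)
  membership <- data.frame(
    gene = unlist(modules$members, use.names = FALSE),
    module = rep(names(modules$members), lengths(modules$members)),
    stringsAsFactors = FALSE)
  write.table(membership, file.path(out_dir, "module_membership.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(modules$summary, file.path(out_dir, "module_summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  stages$modules <- list(n_clusters = part$n_clusters,
                         n_modules = length(modules$members))

  inputs <- c("expression.tsv", "compendium_ranks.tsv",
              "compendium_instances.tsv", "gene_sets.gmt",
              "network_edges.tsv",
              sprintf("topology_%s.tsv", names(topologies)))
  manifest <- list(
    parameters = unclass(config),
    seed = config$seed,
    input_checksums = as.list(setNames(
      unname(tools::md5sum(file.path(out_dir, inputs))), inputs)),
    stages = stages)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(expr = expr, truth = truth, compendium = compendium,
                 collection = collection, topologies = topologies,
                 patterns = patt, merged = merged, signature = sig,
                 cmap = cmap, enrich_up = enr_up, enrich_down = enr_down,
                 activity = act, spia = spia_tab, modules = modules,
                 manifest = manifest))
}
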