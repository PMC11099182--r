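#!/usr/bin/env Rscript
# Stage 1: generate the ground-truthed study inputs.
#
# Emulates the two data modalities the downstream stages consume: an
# AIRR-style rearrangement table of paired heavy/light BCR contigs with
# clonal structure, SHM and decoy contigs, and a negative-binomial UMI count
# matrix with a gene module planted in one transcriptional cluster.

suppressPackageStartupMessages(library(bcrtrace))
dir.create("results/simulated", showWarnings = FALSE, recursive = TRUE)

seed <- 20240917L

rep_cfg <- repertoire_sim_config(n_cells = 200, n_clones = 30,
                                 shm_rate = 0.02, seed = seed)
sim <- simulate_repertoire(rep_cfg)
write_airr(sim$rearrangements, "results/simulated/rearrangements.tsv")
jsonlite::write_json(
  list(family_of_cell = as.list(sim$truth$family_of_cell),
       unpaired_cells = sim$truth$unpaired_cells),
  "results/simulated/repertoire_truth.json", auto_unbox = TRUE)
cat("Simulated", length(sim$truth$family_of_cell), "cells in",
    nrow(sim$truth$clone_table), "clones;",
    nrow(sim$rearrangements), "contigs written\n")

expr_cfg <- expression_sim_config(
  n_genes = 2000, n_cells = 1000, n_clusters = 5,
  module_specs = list(list(name = "recruitment_module", n_genes = 50,
                           clusters = 1, effect = 1.0)),
  seed = seed)
esim <- simulate_expression(expr_cfg)
write_mtx(esim$counts, "results/simulated/counts")
utils::write.table(esim$cells, "results/simulated/cell_annotations.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
write_gmt(esim$truth$module_genes, "results/simulated/true_modules.gmt")
cat("Simulated", nrow(esim$counts), "genes x", ncol(esim$counts),
    "cells; module of 50 genes planted in cluster 1\n")

run_report("results/simulated/run_report.json",
           simulate_repertoire = list(seed = seed, n_cells = 200,
                                      n_clones = 30, shm_rate = 0.02),
           simulate_expression = list(seed = seed, n_genes = 2000,
                                      n_cells = 1000, effect = 1.0))
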