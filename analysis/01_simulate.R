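#!/usr/bin/env Rscript

# Stage 1 — synthetic study data.
#
# Generates the two-group liver-expression dataset the downstream stages
# screen: CK (untreated diabetic control) vs RS (resistant-starch treated),
# 4 biological replicates per group, 1000 genes with ~5% planted up at fold
# change 2.5 and ~5% down at 0.4, log2 replicate noise 0.25, plus a
# 38-pathway annotation and a disease gene list with known ground truth.

suppressPackageStartupMessages(library(rslgn))

out <- "results/simulation"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- simulation_config(seed = 1L)
sim <- simulate_expression(cfg)
pc <- simulate_pathways(cfg, sim$truth)
dg <- simulate_disease_genes(sim$truth, cfg$frac_disease_genes, cfg$seed + 2L)

write_expression(sim$matrix, file.path(out, "expression.tsv"))
write_truth(sim$truth, file.path(out, "truth.tsv"))
write_gmt(pc, file.path(out, "pathways.gmt"))
write_gene_list(dg, file.path(out, "disease_genes.txt"))

n_de <- sum(sim$truth$true_status != "null")
cat(sprintf("simulated %d genes x %d samples; %d planted DE (%d up, %d down)\n",
            cfg$n_genes, ncol(sim$matrix), n_de,
            sum(sim$truth$true_status == "up"),
            sum(sim$truth$true_status == "down")))
cat(sprintf("pathway annotation: %d sets, sizes %d-%d; disease list: %d genes\n",
            length(pc), min(lengths(pc)), max(lengths(pc)), length(dg)))
cat(sprintf("outputs under %s\n", out))
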