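#!/usr/bin/env Rscript

# Stage 3 — local gene network assembly.
#
# Maps the screened genes onto the disease gene list, anchors pathways on
# the disease-associated DEGs, links pathways that share member genes, and
# decomposes the result into a main network and isolated pathways. Also
# reconstructs the published forkhead class A signaling hub from its
# printed pathway-link list.

suppressPackageStartupMessages(library(rslgn))

out <- "results/network"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

deg <- read_deg_table("results/screen/degs_simulated.tsv")
pc <- read_gmt("results/simulation/pathways.gmt")
dg <- read_gene_list("results/simulation/disease_genes.txt")

dd <- map_disease_genes(deg, dg)
cat(sprintf("disease-associated DEGs: %d (%d up, %d down)\n",
            nrow(dd), sum(dd$call == "up"), sum(dd$call == "down")))

g <- build_lgn(dd, pc, disease_genes = dg, include_neighbor_genes = TRUE)
write_lgn(g, file.path(out, "lgn_edges.tsv"))
comp <- decompose_lgn(g)
cat(sprintf("LGN: %d nodes, %d edges; %d component(s); main has %d nodes; %d isolated pathway(s)\n",
            igraph::vcount(g), igraph::ecount(g), length(comp$components),
            length(comp$main), length(comp$isolated_pathways)))

fh <- lgn_from_links(load_fixture("forkhead_links"))
write_lgn(fh, file.path(out, "forkhead_hub_edges.tsv"))
dp <- degree_profile(fh, "pathway_pathway")
cat(sprintf("forkhead class A signaling hub (R1): pathway-link degree %d\n",
            dp$degrees[["R1"]]))
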