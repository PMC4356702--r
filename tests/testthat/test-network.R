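toy_degs <- function() {
  screen_degs(c(Cpt1a = 2.24, Gck = 0.40, Actb = 1.0, G6pc = 2.35))
}

test_that("disease-gene mapping keeps regulated disease genes, case-insensitively", {
  degs <- toy_degs()
  expect_equal(nrow(map_disease_genes(degs, c("Cpt1a", "Gck", "Actb"))), 2)
  expect_warning(empty <- map_disease_genes(degs, c("Foxa1")), "no differentially")
  expect_equal(nrow(empty), 0)
  one <- map_disease_genes(degs, c("CPT1A"))
  expect_identical(one$gene_id, "Cpt1a")   # DEG spelling preserved
})

test_that("LGN assembly anchors pathways on disease DEGs and derives shared-member links", {
  degs <- toy_degs()
  dd <- map_disease_genes(degs, c("Cpt1a", "Gck", "G6pc", "Hnf4a"))
  pc <- pathway_collection(list(
    R5 = c("G6pc", "Gck", "Hnf4a"),
    R28 = c("Gck", "Pklr"),
    R99 = c("Foxa1", "Actb")       # no disease DEG: excluded
  ))
  g <- build_lgn(dd, pc)
  v <- igraph::V(g)
  expect_setequal(v$name[v$node_type == "pathway"], c("R5", "R28"))
  expect_setequal(v$name[v$node_type == "gene"], c("G6pc", "Gck"))
  et <- igraph::E(g)$edge_type
  expect_equal(sum(et == "membership"), 3)   # G6pc-R5, Gck-R5, Gck-R28
  expect_equal(sum(et == "pathway_link"), 1) # R5-R28 share Gck
})

test_that("neighbor disease genes enter with regulation none", {
  degs <- toy_degs()
  dd <- map_disease_genes(degs, c("Gck", "Hnf4a"))
  pc <- pathway_collection(list(R5 = c("Gck", "Hnf4a", "Pklr")))
  g <- build_lgn(dd, pc, disease_genes = c("Gck", "Hnf4a"),
                 include_neighbor_genes = TRUE)
  v <- igraph::V(g)
  expect_identical(v$regulation[v$name == "Hnf4a"], "none")
  expect_identical(v$regulation[v$name == "Gck"], "down")
  # without the flag the neighbor stays out
  g2 <- build_lgn(dd, pc, disease_genes = c("Gck", "Hnf4a"))
  expect_false("Hnf4a" %in% igraph::V(g2)$name)
})

test_that("no disease DEGs gives an empty graph; bad links are input errors", {
  degs <- toy_degs()
  pc <- pathway_collection(list(R5 = c("G6pc", "Gck")))
  suppressWarnings(dd0 <- map_disease_genes(degs, "Foxa1"))
  expect_equal(igraph::vcount(build_lgn(dd0, pc)), 0)
  dd <- map_disease_genes(degs, c("Gck"))
  expect_error(build_lgn(dd, pc, links = data.frame(from = "R5", to = "R77")),
               "R77", class = "rslgn_input_error")
})

test_that("explicit link fixtures override derivation: the forkhead hub has degree 8", {
  fl <- load_fixture("forkhead_links")
  g <- lgn_from_links(fl)
  dp <- degree_profile(g, "pathway_pathway")
  expect_equal(unname(dp$degrees["R1"]), 8)
  expect_equal(igraph::vcount(g), 9)
  # same structure through build_lgn with one anchoring DEG per pathway
  degs <- screen_degs(setNames(rep(3, 9), paste0("gene", 1:9)))
  pc <- pathway_collection(setNames(lapply(1:9, function(i) paste0("gene", i)),
                                    unique(c(fl$from, fl$to))))
  g2 <- build_lgn(map_disease_genes(degs, degs$gene_id), pc,
                  links = fl[c("from", "to")])
  expect_equal(unname(degree_profile(g2, "pathway_pathway")$degrees["R1"]), 8)
})

test_that("component decomposition matches union-find and breaks ties lexicographically", {
  # two disjoint stars of sizes 4 and 3
  g <- lgn_graph(
    genes = data.frame(gene_id = c("a", "b", "c", "d", "e"),
                       regulation = rep("up", 5)),
    pathways = data.frame(pathway_id = c("P1", "P2"), pathway_name = c("p1", "p2")),
    membership = data.frame(gene_id = c("a", "b", "c", "d", "e"),
                            pathway_id = c("P1", "P1", "P1", "P2", "P2"))
  )
  comp <- decompose_lgn(g)
  expect_equal(comp$sizes, c(4L, 3L))
  expect_setequal(comp$main, c("a", "b", "c", "P1"))
  expect_identical(comp$isolated_pathways, "P2")

  # random graphs against the union-find oracle
  set.seed(42)
  for (i in 1:10) {
    a <- random_adjacency(50, 0.03)
    gg <- adjacency_to_igraph(a)
    got <- decompose_lgn(gg)$components
    want <- oracle_components(a)
    want <- lapply(want, sort)
    want <- want[order(-lengths(want), vapply(want, min, character(1)))]
    expect_identical(got, unname(want))
  }
})

test_that("one-mode projections equal the brute-force pair scan", {
  # star of one pathway with three members projects to a gene triangle
  memb <- data.frame(gene_id = c("x", "y", "z"), pathway_id = "P1")
  g <- lgn_graph(genes = data.frame(gene_id = c("x", "y", "z"), regulation = "up"),
                 pathways = data.frame(pathway_id = "P1", pathway_name = "p"),
                 membership = memb)
  gg <- project_lgn(g, "gene_gene")
  expect_equal(igraph::ecount(gg), 3)

  # two pathways, no shared genes, no links: empty pathway projection
  g2 <- lgn_graph(genes = data.frame(gene_id = c("x", "y"), regulation = "up"),
                  pathways = data.frame(pathway_id = c("P1", "P2"),
                                        pathway_name = c("p1", "p2")),
                  membership = data.frame(gene_id = c("x", "y"),
                                          pathway_id = c("P1", "P2")))
  expect_equal(igraph::ecount(project_lgn(g2, "pathway_pathway")), 0)

  # random bipartite membership vs double-loop oracle
  set.seed(7)
  for (i in 1:5) {
    genes <- sprintf("g%02d", 1:20)
    paths <- sprintf("P%d", 1:6)
    memb <- unique(data.frame(
      gene_id = sample(genes, 40, replace = TRUE),
      pathway_id = sample(paths, 40, replace = TRUE)))
    g3 <- lgn_graph(genes = data.frame(gene_id = genes, regulation = "up"),
                    pathways = data.frame(pathway_id = paths, pathway_name = paths),
                    membership = memb)
    for (mode in c("gene_gene", "pathway_pathway")) {
      got <- edge_set(project_lgn(g3, mode))
      want <- sort(vapply(oracle_projection(memb, mode),
                          paste, character(1), collapse = "|"))
      expect_identical(got, want)
    }
  }
})

test_that("projection never disconnects co-membership components", {
  sim <- simulate_expression(simulation_config(n_genes = 300, seed = 19))
  pc <- simulate_pathways(simulation_config(n_genes = 300, seed = 19), sim$truth)
  degs <- run_deg_screen(sim$matrix, screen_params(seed = 19))
  dd <- map_disease_genes(degs, sim$truth$gene_id)
  g <- build_lgn(dd, pc)
  ntype <- setNames(igraph::V(g)$node_type, igraph::V(g)$name)
  # membership-only graph: pathway_link edges bridge pathways through genes
  # outside the network, so co-membership is the structure projections keep
  memb_only <- igraph::subgraph_from_edges(
    g, igraph::E(g)[igraph::E(g)$edge_type == "membership"],
    delete.vertices = FALSE)
  memb_comp <- decompose_lgn(memb_only)
  for (mode in c("gene_gene", "pathway_pathway")) {
    keep_type <- if (mode == "gene_gene") "gene" else "pathway"
    proj_comp <- decompose_lgn(project_lgn(g, mode))
    n_with_type <- sum(vapply(memb_comp$components,
                              function(cc) any(ntype[cc] == keep_type),
                              logical(1)))
    expect_lte(length(proj_comp$components), n_with_type)
  }
})

test_that("graph attributes survive an export/import round trip", {
  degs <- toy_degs()
  dd <- map_disease_genes(degs, c("Cpt1a", "Gck", "G6pc"))
  pc <- pathway_collection(list(R5 = c("G6pc", "Gck"), R3 = c("Cpt1a", "Gck")))
  g <- build_lgn(dd, pc)
  path <- withr::local_tempfile(fileext = ".tsv")
  gml <- write_lgn(g, path)[2]
  g2 <- read_lgn(gml)
  expect_identical(edge_set(g2), edge_set(g))
  o <- match(igraph::V(g)$name, igraph::V(g2)$name)
  expect_identical(igraph::V(g2)$regulation[o], igraph::V(g)$regulation)
  expect_identical(igraph::V(g2)$node_type[o], igraph::V(g)$node_type)
})
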