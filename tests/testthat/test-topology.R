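triangle <- function() adjacency_to_igraph(
  matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3, 3,
         dimnames = list(c("A", "B", "C"), c("A", "B", "C"))))

test_that("degree profile matches forced and oracle values", {
  tri <- triangle()
  dp <- degree_profile(tri, "full")
  expect_equal(unname(dp$degrees), c(2, 2, 2))
  expect_equal(dp$average_degree, 2)

  set.seed(5)
  for (i in 1:5) {
    a <- random_adjacency(30, 0.1)
    dp <- degree_profile(adjacency_to_igraph(a), "full")
    expect_equal(dp$degrees[rownames(a)], oracle_degrees(a), ignore_attr = TRUE)
  }
})

test_that("average path length matches hand enumeration and the Floyd-Warshall oracle", {
  # path graph on 3 nodes: (1 + 1 + 2) / 3
  pth <- adjacency_to_igraph(matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3, 3,
                                    dimnames = list(letters[1:3], letters[1:3])))
  expect_equal(average_path_length(pth), 4 / 3)
  expect_equal(average_path_length(igraph::make_full_graph(5)), 1)

  set.seed(11)
  for (i in 1:5) {
    a <- random_adjacency(40, 0.07)
    expect_equal(average_path_length(adjacency_to_igraph(a)),
                 oracle_avg_path_length(a), tolerance = 1e-12)
  }
})

test_that("clustering coefficient matches convention extremes and triangle enumeration", {
  expect_equal(clustering_coefficient(igraph::make_full_graph(6))$global, 1)
  star <- igraph::make_star(6, mode = "undirected")
  expect_equal(clustering_coefficient(star)$global, 0)

  set.seed(13)
  for (i in 1:5) {
    a <- random_adjacency(30, 0.15)
    got <- clustering_coefficient(adjacency_to_igraph(a))$global
    expect_equal(got, oracle_clustering(a)$global, tolerance = 1e-12)
  }
})

test_that("power-law fit recovers an exact power law and refuses degenerate input", {
  k <- 1:6
  counts <- setNames(as.integer(round(1000 * k^-2)), k)
  fit <- scale_free_fit(counts)
  expect_equal(fit$exponent, 2, tolerance = 1e-2)   # rounding of counts only
  expect_gt(fit$fit_r2, 0.999)

  expect_true(is.na(scale_free_fit(setNames(c(5L, 5L), c(2, 3)))$exponent))
})

test_that("a preferential-attachment graph yields a plausible scale-free exponent", {
  g <- with_seed_local <- local({
    set.seed(11)
    igraph::sample_pa(500, m = 2, directed = FALSE)
  })
  fit <- scale_free_fit(igraph::degree(g))
  expect_gt(fit$exponent, 1.5)
  expect_lt(fit$exponent, 3.5)
})

test_that("metrics are invariant under node relabeling", {
  set.seed(17)
  a <- random_adjacency(25, 0.15)
  g <- adjacency_to_igraph(a)
  perm <- sample(25)
  b <- a[perm, perm]
  g2 <- adjacency_to_igraph(b)
  expect_equal(average_path_length(g2), average_path_length(g))
  expect_equal(clustering_coefficient(g2)$global, clustering_coefficient(g)$global)
  expect_equal(degree_profile(g2, "full")$average_degree,
               degree_profile(g, "full")$average_degree)
})

test_that("an isolated node changes neither path length nor clustering of the main component", {
  set.seed(19)
  a <- random_adjacency(20, 0.2)
  g <- adjacency_to_igraph(a)
  g2 <- igraph::add_vertices(g, 1, name = "zzz_isolated")
  expect_equal(average_path_length(g2), average_path_length(g))
  expect_equal(clustering_coefficient(g2)$global, clustering_coefficient(g)$global)
})

test_that("adding an edge never increases the main component's average path length", {
  set.seed(23)
  for (i in 1:5) {
    a <- random_adjacency(20, 0.15)
    g <- adjacency_to_igraph(a)
    main <- decompose_lgn(g)$main
    if (length(main) < 3) next
    # add an edge within the main component
    pair <- NULL
    for (x in main) for (y in main) {
      if (x < y && a[x, y] == 0) { pair <- c(x, y); break }
    }
    if (is.null(pair)) next
    g2 <- igraph::add_edges(g, match(pair, igraph::V(g)$name))
    expect_lte(average_path_length(g2), average_path_length(g) + 1e-12)
  }
})

test_that("the full topology summary is coherent across views", {
  sim <- simulate_expression(simulation_config(n_genes = 200, seed = 29))
  pc <- simulate_pathways(simulation_config(n_genes = 200, seed = 29), sim$truth)
  degs <- run_deg_screen(sim$matrix, screen_params(seed = 29))
  g <- build_lgn(map_disease_genes(degs, sim$truth$gene_id), pc)
  ts <- topology_summary(g)
  expect_named(ts, c("full", "gene_gene", "pathway_pathway"))
  for (view in names(ts)) {
    s <- ts[[view]]
    expect_equal(sum(s$degree_distribution), length(s$degrees))
    expect_true(is.na(s$clustering_coefficient) ||
                  (s$clustering_coefficient >= 0 && s$clustering_coefficient <= 1))
    expect_true(is.na(s$average_path_length) || s$average_path_length >= 1)
  }
  # gene degrees in the full view count pathway memberships
  memb <- igraph::E(g)$edge_type == "membership"
  el <- igraph::as_edgelist(g)[memb, , drop = FALSE]
  some_gene <- el[1, 1]
  expect_equal(unname(ts$full$degrees[some_gene]), sum(el[, 1] == some_gene))
})
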