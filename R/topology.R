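#' Degree profile of a network view
#'
#' Degrees are reported per view because the study's anecdotes mix views: a
#' gene participating in ~3 pathways is a degree in the full typed graph,
#' while the forkhead hub's degree of 8 counts pathway-pathway links only.
#'
#' @param graph an [lgn_graph()] or any igraph.
#' @param view `"full"` (the typed graph as-is), `"gene_gene"` or
#'   `"pathway_pathway"` (one-mode projections, see [project_lgn()]).
#' @return list with `degrees` (named integer vector) and `average_degree`.
#' @export
degree_profile <- function(graph, view = c("full", "gene_gene", "pathway_pathway")) {
  view <- match.arg(view)
  g <- if (view == "full") graph else project_lgn(graph, view)
  if (igraph::vcount(g) == 0L) input_error("graph has no nodes in the requested view")
  d <- igraph::degree(g)
  list(degrees = d, average_degree = mean(d))
}

# Largest connected component as an induced subgraph, using the
# decompose_lgn ordering (size, then smallest minimum node id).
main_component <- function(g) {
  if (igraph::vcount(g) == 0L) return(g)
  main <- decompose_lgn(g)$main
  if (is.null(igraph::V(g)$name)) main <- as.integer(main)
  igraph::induced_subgraph(g, main)
}

#' Average shortest-path length of the main component
#'
#' Mean breadth-first-search distance over all unordered connected node
#' pairs within the largest connected component; other components are
#' excluded by construction, so adding an isolated node never changes the
#' value. Undefined (NA) when the main component has no edges.
#'
#' @param graph an igraph (any view).
#' @return scalar, or `NA_real_` when undefined.
#' @export
average_path_length <- function(graph) {
  g <- main_component(graph)
  if (igraph::vcount(g) < 2L || igraph::ecount(g) == 0L) return(NA_real_)
  igraph::mean_distance(g, directed = FALSE, unconnected = FALSE)
}

#' Clustering coefficient (Watts-Strogatz convention)
#'
#' Local clustering of a node with degree >= 2 is
#' `2 * triangles / (deg * (deg - 1))`; nodes of degree < 2 contribute 0
#' and are counted. The global coefficient is the mean over all nodes of
#' the main component.
#'
#' @param graph an igraph (any view).
#' @return list with `global` (scalar in `[0, 1]`) and `local` (named
#'   vector over main-component nodes).
#' @export
clustering_coefficient <- function(graph) {
  g <- main_component(graph)
  if (igraph::vcount(g) == 0L) input_error("graph has no nodes")
  loc <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  names(loc) <- igraph::V(g)$name
  list(global = mean(loc), local = loc)
}

#' Heuristic power-law fit to a degree distribution
#'
#' Ordinary least squares of `log10(count)` on `log10(degree)` over degrees
#' >= 1 with nonzero counts. This is the classic visual scale-free
#' diagnostic, not a hypothesis test; it requires at least 3 distinct
#' degrees and refuses (returns NAs) otherwise.
#'
#' @param degree_distribution named integer vector, degree -> node count
#'   (as produced by [topology_summary()]), or a plain degree vector.
#' @return list with `exponent` (= minus the fitted slope) and `fit_r2`.
#' @export
scale_free_fit <- function(degree_distribution) {
  x <- degree_distribution
  if (is.null(names(x))) {           # raw degrees: tabulate first
    tab <- table(x)
    x <- stats::setNames(as.integer(tab), names(tab))
  }
  k <- as.numeric(names(x))
  keep <- k >= 1 & x > 0
  k <- k[keep]
  cnt <- as.numeric(x[keep])
  if (length(unique(k)) < 3L) {
    return(list(exponent = NA_real_, fit_r2 = NA_real_))
  }
  fit <- stats::lm(log10(cnt) ~ log10(k))
  list(exponent = -unname(stats::coef(fit)[2L]),
       fit_r2 = summary(fit)$r.squared)
}

#' Full topology characterization of an LGN
#'
#' Computes, for each of the three views (full typed graph, gene-gene
#' projection, pathway-pathway projection): per-node degrees, average
#' degree, average shortest-path length and clustering coefficient of the
#' main component, component decomposition, the degree distribution and its
#' heuristic power-law fit.
#'
#' @param graph an [lgn_graph()].
#' @param views character vector of views to compute (default all three).
#' @return list of class `"topology_summary"`, one entry per view, each
#'   with keys `degrees`, `average_degree`, `average_path_length`,
#'   `clustering_coefficient`, `n_components`, `main_component_size`,
#'   `n_isolated_pathways`, `degree_distribution`, `powerlaw_exponent`,
#'   `fit_r2`.
#' @export
topology_summary <- function(graph,
                             views = c("full", "gene_gene", "pathway_pathway")) {
  views <- match.arg(views, several.ok = TRUE)
  out <- lapply(views, function(view) {
    g <- if (view == "full") graph else project_lgn(graph, view)
    if (igraph::vcount(g) == 0L) {
      return(list(degrees = stats::setNames(integer(), character()),
                  average_degree = NA_real_, average_path_length = NA_real_,
                  clustering_coefficient = NA_real_, n_components = 0L,
                  main_component_size = 0L, n_isolated_pathways = 0L,
                  degree_distribution = stats::setNames(integer(), character()),
                  powerlaw_exponent = NA_real_, fit_r2 = NA_real_))
    }
    dp <- degree_profile(g, "full")
    comp <- decompose_lgn(g)
    dd_tab <- table(dp$degrees)
    dd <- stats::setNames(as.integer(dd_tab), names(dd_tab))
    pl <- scale_free_fit(dd)
    list(degrees = dp$degrees,
         average_degree = dp$average_degree,
         average_path_length = average_path_length(g),
         clustering_coefficient = clustering_coefficient(g)$global,
         n_components = length(comp$components),
         main_component_size = length(comp$main),
         n_isolated_pathways = length(comp$isolated_pathways),
         degree_distribution = dd,
         powerlaw_exponent = pl$exponent,
         fit_r2 = pl$fit_r2)
  })
  names(out) <- views
  class(out) <- "topology_summary"
  out
}

#' @export
print.topology_summary <- function(x, ...) {
  for (view in names(x)) {
    s <- x[[view]]
    cat(sprintf("[%s] nodes: %d | avg degree: %.3f | path length: %.3f | clustering: %.3f | components: %d (main %d)\n",
                view, length(s$degrees), s$average_degree,
                s$average_path_length, s$clustering_coefficient,
                s$n_components, s$main_component_size))
  }
  invisible(x)
}
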