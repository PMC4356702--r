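#' Write an LGN graph as edge-list TSV and GraphML
#'
#' Two files: `<path>` gets the edge list (`source`, `target`, `edge_type`)
#' and `<path>` with extension `.graphml` gets the full attributed graph
#' (vertex attributes `node_type`, `regulation`, `pathway_name`; edge
#' attribute `edge_type`).
#'
#' @param graph an [lgn_graph()].
#' @param path output path for the edge-list TSV; the GraphML path is
#'   derived from it by swapping the extension.
#' @return character vector of the two paths written, invisibly.
#' @export
write_lgn <- function(graph, path) {
  el <- igraph::as_edgelist(graph)
  et <- igraph::E(graph)$edge_type
  df <- data.frame(source = el[, 1L], target = el[, 2L],
                   edge_type = if (length(et)) et else character(),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  gml <- sub("\\.[^.]*$", "", path)
  gml <- paste0(gml, ".graphml")
  igraph::write_graph(graph, gml, format = "graphml")
  invisible(c(path, gml))
}

#' Read an LGN graph back from GraphML
#' @param path a `.graphml` file written by [write_lgn()].
#' @return an [lgn_graph()].
#' @export
read_lgn <- function(path) {
  if (!file.exists(path)) format_error(sprintf("graph file not found: %s", path))
  g <- igraph::read_graph(path, format = "graphml")
  vat <- igraph::vertex_attr_names(g)
  if (!all(c("node_type") %in% vat)) {
    format_error(sprintf("'%s' lacks the node_type vertex attribute", path))
  }
  # GraphML has no NA: missing attribute values come back as "" or "NA"
  for (at in intersect(c("regulation", "pathway_name"), vat)) {
    v <- igraph::vertex_attr(g, at)
    v[v %in% c("", "NA")] <- NA_character_
    g <- igraph::set_vertex_attr(g, at, value = v)
  }
  class(g) <- c("lgn_graph", class(g))
  g
}

#' Read an edge list TSV (source, target[, edge_type])
#' @param path file path.
#' @return data.frame with columns `source`, `target`, `edge_type`.
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) format_error(sprintf("edge list not found: %s", path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("source", "target") %in% names(df))) {
    format_error(sprintf("'%s' must have columns source and target", path))
  }
  if (!"edge_type" %in% names(df)) df$edge_type <- NA_character_
  df[c("source", "target", "edge_type")]
}

#' Write a topology summary as a flat JSON report
#'
#' One object per view; the per-node degree map and the degree distribution
#' are emitted as JSON objects keyed by node id / degree, every metric as a
#' bare number (`null` when undefined).
#'
#' @param summary a [topology_summary()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_topology <- function(summary, path) {
  stopifnot(inherits(summary, "topology_summary"))
  out <- lapply(summary, function(s) {
    list(average_degree = s$average_degree,
         average_path_length = s$average_path_length,
         clustering_coefficient = s$clustering_coefficient,
         n_components = s$n_components,
         main_component_size = s$main_component_size,
         n_isolated_pathways = s$n_isolated_pathways,
         powerlaw_exponent = s$powerlaw_exponent,
         fit_r2 = s$fit_r2,
         degrees = as.list(s$degrees),
         degree_distribution = as.list(s$degree_distribution))
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}
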