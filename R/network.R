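#' Construct a validated local gene network graph
#'
#' The local gene network (LGN) is a typed undirected graph with two node
#' classes — genes (carrying a `regulation` attribute, `up`/`down`/`none`)
#' and pathways (carrying a display name) — and two edge classes:
#' `membership` (gene-pathway) and `pathway_link` (pathway-pathway).
#' Self-loops and parallel edges of the same type are rejected; the graph
#' is undirected throughout because the underlying annotation asserts no
#' direction.
#'
#' @param genes data.frame with columns `gene_id` and `regulation`
#'   (`up`, `down` or `none`); may have zero rows.
#' @param pathways data.frame with columns `pathway_id` and `pathway_name`;
#'   may have zero rows.
#' @param membership data.frame with columns `gene_id`, `pathway_id`.
#' @param links data.frame with columns `from`, `to` (pathway ids), or NULL.
#' @return an `igraph` object of class `c("lgn_graph", "igraph")` with
#'   vertex attributes `node_type` (`gene`/`pathway`), `regulation`,
#'   `pathway_name`, and edge attribute `edge_type`.
#' @export
lgn_graph <- function(genes, pathways, membership, links = NULL) {
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  pathways <- as.data.frame(pathways, stringsAsFactors = FALSE)
  membership <- as.data.frame(membership, stringsAsFactors = FALSE)
  if (nrow(genes) && !all(genes$regulation %in% c("up", "down", "none"))) {
    input_error("gene regulation must be one of up, down, none")
  }
  if (anyDuplicated(genes$gene_id) || anyDuplicated(pathways$pathway_id)) {
    input_error("gene and pathway ids must be unique")
  }
  both <- intersect(genes$gene_id, pathways$pathway_id)
  if (length(both)) {
    input_error(sprintf("identifier(s) used as both gene and pathway: %s",
                        paste(both, collapse = ", ")))
  }
  if (nrow(membership)) {
    bad_g <- setdiff(membership$gene_id, genes$gene_id)
    bad_p <- setdiff(membership$pathway_id, pathways$pathway_id)
    if (length(bad_g) || length(bad_p)) {
      input_error(sprintf("membership edge references unknown node(s): %s",
                          paste(c(bad_g, bad_p), collapse = ", ")))
    }
    if (anyDuplicated(membership[c("gene_id", "pathway_id")])) {
      input_error("parallel membership edges are not allowed")
    }
  }
  if (!is.null(links) && nrow(links)) {
    links <- as.data.frame(links, stringsAsFactors = FALSE)
    bad <- setdiff(c(links$from, links$to), pathways$pathway_id)
    if (length(bad)) {
      input_error(sprintf("pathway_link references absent pathway id(s): %s",
                          paste(unique(bad), collapse = ", ")))
    }
    if (any(links$from == links$to)) {
      input_error("pathway_link self-loops are not allowed")
    }
    key <- apply(cbind(pmin(links$from, links$to), pmax(links$from, links$to)),
                 1L, paste, collapse = "\r")
    if (anyDuplicated(key)) {
      input_error("parallel pathway_link edges are not allowed")
    }
  }
  vdf <- data.frame(
    name = c(genes$gene_id, pathways$pathway_id),
    node_type = c(rep("gene", nrow(genes)), rep("pathway", nrow(pathways))),
    regulation = c(if (nrow(genes)) genes$regulation, rep(NA_character_, nrow(pathways))),
    pathway_name = c(rep(NA_character_, nrow(genes)), if (nrow(pathways)) pathways$pathway_name),
    stringsAsFactors = FALSE
  )
  edf <- data.frame(from = character(), to = character(), edge_type = character(),
                    stringsAsFactors = FALSE)
  if (nrow(membership)) {
    edf <- rbind(edf, data.frame(from = membership$gene_id, to = membership$pathway_id,
                                 edge_type = "membership", stringsAsFactors = FALSE))
  }
  if (!is.null(links) && nrow(links)) {
    edf <- rbind(edf, data.frame(from = links$from, to = links$to,
                                 edge_type = "pathway_link", stringsAsFactors = FALSE))
  }
  g <- igraph::graph_from_data_frame(edf, directed = FALSE, vertices = vdf)
  class(g) <- c("lgn_graph", class(g))
  g
}

#' Restrict a differential-expression table to disease-associated genes
#'
#' Keeps the genes called `up` or `down` whose symbol appears in the
#' disease gene set; matching is case-insensitive after whitespace
#' trimming, and the DEG table's spelling is preserved in the output. An
#' empty intersection is legitimate (warning, not an error).
#'
#' @param degs a `deg_table` (see [screen_degs()]).
#' @param disease character vector of disease-associated gene symbols.
#' @return the disease-associated subtable of `degs`.
#' @export
map_disease_genes <- function(degs, disease) {
  if (!all(c("gene_id", "call") %in% names(degs))) {
    input_error("`degs` must have columns gene_id and call")
  }
  keep <- degs$call %in% c("up", "down") &
    symbol_key(degs$gene_id) %in% symbol_key(disease)
  out <- degs[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L) {
    warning("no differentially expressed gene matches the disease gene set",
            call. = FALSE)
  }
  out
}

#' Assemble the local gene network
#'
#' A pathway enters the LGN iff it contains at least one disease-associated
#' differentially expressed gene; membership edges connect it to all such
#' members. With `include_neighbor_genes`, other disease-set genes that
#' participate in an included pathway are added as `regulation = "none"`
#' nodes with their membership edges (the "other highlighted genes" of the
#' published network figure). Pathway-pathway links are taken verbatim from
#' `links` when supplied (restricted to included pathways); otherwise two
#' included pathways are linked iff they share at least one member gene in
#' the annotation.
#'
#' @param disease_degs disease-associated DEG subtable from
#'   [map_disease_genes()].
#' @param pathways a [pathway_collection()].
#' @param disease_genes full disease gene set (needed only when
#'   `include_neighbor_genes = TRUE`).
#' @param include_neighbor_genes logical; add non-DE disease genes of the
#'   included pathways.
#' @param links optional explicit pathway-link edge list (data.frame
#'   `from`, `to`); ids must exist in `pathways`.
#' @return an [lgn_graph()].
#' @export
build_lgn <- function(disease_degs, pathways, disease_genes = NULL,
                      include_neighbor_genes = FALSE, links = NULL) {
  stopifnot(inherits(pathways, "pathway_collection"))
  if (!is.null(links) && nrow(as.data.frame(links))) {
    links <- as.data.frame(links, stringsAsFactors = FALSE)
    bad <- setdiff(unique(c(links$from, links$to)), names(pathways))
    if (length(bad)) {
      input_error(sprintf("link references pathway id(s) absent from the collection: %s",
                          paste(bad, collapse = ", ")))
    }
  }
  deg_ids <- disease_degs$gene_id
  deg_key <- symbol_key(deg_ids)
  member_keys <- lapply(pathways, symbol_key)
  anchored <- vapply(member_keys, function(k) any(deg_key %in% k), logical(1L))
  inc <- names(pathways)[anchored]
  if (length(inc) == 0L) {
    return(lgn_graph(genes = data.frame(gene_id = character(), regulation = character()),
                     pathways = data.frame(pathway_id = character(), pathway_name = character()),
                     membership = data.frame(gene_id = character(), pathway_id = character())))
  }
  reg <- ifelse(disease_degs$call == "up", "up", "down")
  names(reg) <- deg_key
  mem <- list()
  gene_reg <- stats::setNames(character(), character())
  for (p in inc) {
    k <- member_keys[[p]]
    hit <- deg_key %in% k
    for (g in deg_ids[hit]) {
      mem[[length(mem) + 1L]] <- c(g, p)
      gene_reg[symbol_key(g)] <- reg[[symbol_key(g)]]
    }
    if (isTRUE(include_neighbor_genes) && !is.null(disease_genes)) {
      dkey <- symbol_key(disease_genes)
      nb <- disease_genes[dkey %in% k & !(dkey %in% deg_key)]
      for (g in nb) {
        mem[[length(mem) + 1L]] <- c(g, p)
        if (!symbol_key(g) %in% names(gene_reg)) gene_reg[symbol_key(g)] <- "none"
      }
    }
  }
  memdf <- as.data.frame(do.call(rbind, mem), stringsAsFactors = FALSE)
  names(memdf) <- c("gene_id", "pathway_id")
  memdf <- unique(memdf)
  # preserve original spelling: first spelling seen per key wins
  genes <- memdf$gene_id[!duplicated(symbol_key(memdf$gene_id))]
  gdf <- data.frame(gene_id = genes,
                    regulation = unname(gene_reg[symbol_key(genes)]),
                    stringsAsFactors = FALSE)
  pn <- attr(pathways, "pathway_names")
  pdf <- data.frame(pathway_id = inc, pathway_name = unname(pn[inc]),
                    stringsAsFactors = FALSE)
  if (is.null(links)) {
    ldf <- derive_pathway_links(pathways, inc)
  } else {
    keep <- links$from %in% inc & links$to %in% inc
    ldf <- links[keep, c("from", "to"), drop = FALSE]
  }
  lgn_graph(gdf, pdf, memdf, links = ldf)
}

# Pathway pairs (within `inc`) sharing >= 1 member gene, case-insensitive.
derive_pathway_links <- function(pathways, inc) {
  out <- list()
  keys <- lapply(pathways[inc], symbol_key)
  if (length(inc) >= 2L) {
    for (i in seq_len(length(inc) - 1L)) {
      for (j in seq((i + 1L), length(inc))) {
        if (length(intersect(keys[[i]], keys[[j]]))) {
          out[[length(out) + 1L]] <- c(inc[i], inc[j])
        }
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(from = character(), to = character(), stringsAsFactors = FALSE))
  }
  df <- as.data.frame(do.call(rbind, out), stringsAsFactors = FALSE)
  names(df) <- c("from", "to")
  df
}

#' Build a pathway-only LGN from an explicit link list
#'
#' Convenience constructor for printed pathway-link sub-structures (for
#' example the forkhead class A signaling hub): pathway nodes are the union
#' of ids in the edge list, with `pathway_link` edges and no gene nodes.
#'
#' @param links data.frame with columns `from`, `to`, and optionally
#'   `to_name` for display names of the target pathways.
#' @return an [lgn_graph()].
#' @export
lgn_from_links <- function(links) {
  links <- as.data.frame(links, stringsAsFactors = FALSE)
  ids <- unique(c(links$from, links$to))
  nm <- stats::setNames(ids, ids)
  if ("to_name" %in% names(links)) {
    nm[links$to] <- links$to_name
  }
  lgn_graph(genes = data.frame(gene_id = character(), regulation = character()),
            pathways = data.frame(pathway_id = ids, pathway_name = unname(nm[ids]),
                                  stringsAsFactors = FALSE),
            membership = data.frame(gene_id = character(), pathway_id = character()),
            links = links[c("from", "to")])
}

#' Decompose an LGN into its connected components
#'
#' Undirected traversal over both edge types. Components are ordered by
#' decreasing node count; ties are broken by the lexicographically smallest
#' minimum node id, making the main component unique. Pathway nodes outside
#' the main component are the "isolated pathways".
#'
#' @param graph an [lgn_graph()] (any igraph works).
#' @return list of class `"lgn_components"`: `components` (list of node-id
#'   vectors), `main` (node ids of the largest component),
#'   `isolated_pathways` (pathway ids outside it), `sizes`.
#' @export
decompose_lgn <- function(graph) {
  if (igraph::vcount(graph) == 0L) {
    return(structure(list(components = list(), main = character(),
                          isolated_pathways = character(), sizes = integer()),
                     class = "lgn_components"))
  }
  comp <- igraph::components(graph)
  ids <- igraph::V(graph)$name
  if (is.null(ids)) ids <- as.character(seq_len(igraph::vcount(graph)))
  groups <- split(ids, comp$membership)
  groups <- lapply(groups, sort)
  ord <- order(-lengths(groups), vapply(groups, min, character(1L)))
  groups <- unname(groups[ord])
  main <- groups[[1L]]
  ntype <- igraph::V(graph)$node_type
  path_ids <- ids[!is.na(ntype) & ntype == "pathway"]
  structure(list(components = groups,
                 main = main,
                 isolated_pathways = sort(setdiff(path_ids, main)),
                 sizes = lengths(groups)),
            class = "lgn_components")
}

#' @export
print.lgn_components <- function(x, ...) {
  cat(sprintf("lgn_components: %d component(s); main has %d node(s); %d isolated pathway(s)\n",
              length(x$components),
              if (length(x$components)) length(x$main) else 0L,
              length(x$isolated_pathways)))
  invisible(x)
}

#' One-mode projections of the LGN
#'
#' `gene_gene`: genes joined iff they share at least one pathway (via
#' membership edges). `pathway_pathway`: pathways joined iff they share at
#' least one member gene or are joined by an explicit `pathway_link` edge.
#' Both are simple undirected graphs without self-loops.
#'
#' @param graph an [lgn_graph()].
#' @param mode `"gene_gene"` or `"pathway_pathway"`.
#' @return a simple undirected `igraph`.
#' @export
project_lgn <- function(graph, mode = c("gene_gene", "pathway_pathway")) {
  mode <- match.arg(mode)
  ntype <- igraph::V(graph)$node_type
  etype <- igraph::E(graph)$edge_type
  memb <- igraph::subgraph_from_edges(graph, igraph::E(graph)[etype == "membership"],
                                      delete.vertices = FALSE)
  igraph::V(memb)$type <- ntype == "pathway"   # bipartite: FALSE gene, TRUE pathway
  proj <- igraph::bipartite_projection(memb)
  if (mode == "gene_gene") {
    g <- igraph::induced_subgraph(proj$proj1, igraph::V(proj$proj1)$name %in%
                                    igraph::V(graph)$name[ntype == "gene"])
    return(igraph::simplify(g))
  }
  pp <- proj$proj2
  pp <- igraph::induced_subgraph(pp, igraph::V(pp)$name %in%
                                   igraph::V(graph)$name[ntype == "pathway"])
  link_e <- igraph::as_edgelist(graph)[etype == "pathway_link", , drop = FALSE]
  if (nrow(link_e)) {
    pp <- igraph::add_edges(pp, t(matrix(match(link_e, igraph::V(pp)$name),
                                         ncol = 2L)))
  }
  igraph::simplify(pp)
}
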