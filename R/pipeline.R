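#' Configure an end-to-end pipeline run
#'
#' A run either starts from a simulation (`sim` given) or from files on
#' disk (`expression_path`), or from an already screened DEG table
#' (`deg_table`, e.g. a published ratio table). Referenced input files must
#' exist at validation time.
#'
#' @param out_dir output directory (created if missing).
#' @param screen a [screen_params()].
#' @param sim optional [simulation_config()]; when given, expression,
#'   pathways and disease genes are simulated and the file inputs below are
#'   ignored.
#' @param expression_path optional expression TSV (see [read_expression()]).
#' @param pathways_path optional GMT file; required unless `sim` or
#'   `pathways` is given.
#' @param pathways optional [pathway_collection()] passed directly.
#' @param disease_genes_path optional gene-list file.
#' @param disease_genes optional character vector passed directly.
#' @param deg_table optional precomputed `deg_table`; skips the expression
#'   and screening stages.
#' @param links optional explicit pathway-link data.frame (`from`, `to`).
#' @param include_neighbor_genes add non-DE disease genes to the network.
#' @param modules named list of ordered gene-symbol vectors to profile.
#' @return a validated list of class `"run_config"`.
#' @export
run_config <- function(out_dir,
                       screen = screen_params(),
                       sim = NULL,
                       expression_path = NULL,
                       pathways_path = NULL,
                       pathways = NULL,
                       disease_genes_path = NULL,
                       disease_genes = NULL,
                       deg_table = NULL,
                       links = NULL,
                       include_neighbor_genes = FALSE,
                       modules = list()) {
  stopifnot(inherits(screen, "screen_params"))
  if (!is.null(sim)) stopifnot(inherits(sim, "simulation_config"))
  for (p in c(expression_path, pathways_path, disease_genes_path)) {
    if (!is.null(p) && !file.exists(p)) {
      config_error(sprintf("input file does not exist: %s", p))
    }
  }
  if (is.null(sim) && is.null(expression_path) && is.null(deg_table)) {
    config_error("provide `sim`, `expression_path` or `deg_table`")
  }
  if (is.null(sim) && is.null(pathways_path) && is.null(pathways)) {
    config_error("provide `sim`, `pathways_path` or `pathways`")
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  structure(list(out_dir = out_dir, screen = screen, sim = sim,
                 expression_path = expression_path,
                 pathways_path = pathways_path, pathways = pathways,
                 disease_genes_path = disease_genes_path,
                 disease_genes = disease_genes, deg_table = deg_table,
                 links = links,
                 include_neighbor_genes = isTRUE(include_neighbor_genes),
                 modules = modules),
            class = "run_config")
}

# Serialize a run_config to a stable string for fingerprinting. The output
# directory is excluded: it locates results and does not affect them.
config_fingerprint <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  flat <- utils::capture.output(utils::str(cfg, digits.d = 15,
                                           vec.len = 1e6, list.len = 1e6))
  fnv1a32(flat)
}

run_stage <- function(name, expr, out_dir) {
  tryCatch(expr, error = function(e) {
    marker <- file.path(out_dir, paste0(name, ".partial"))
    try(writeLines(conditionMessage(e), marker), silent = TRUE)
    abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
          "rslgn_stage_error")
  })
}

#' Run the whole analysis pipeline
#'
#' Stages, in order: simulate (or load) inputs, differential-expression
#' screen, disease-gene mapping and local-gene-network assembly, topology
#' characterization, metabolism-module profiling. Each stage writes its
#' output under `config$out_dir`; a failing stage aborts with the stage
#' name, leaving a `<stage>.partial` marker. Identical config (including
#' seeds) gives identical outputs.
#'
#' @param config a [run_config()].
#' @return the run manifest (list), also written to
#'   `<out_dir>/manifest.json`: config fingerprint, seed, per-stage output
#'   paths, and headline numbers (DEG counts, component sizes, topology
#'   metrics, module summaries).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  od <- config$out_dir
  outputs <- list()
  headline <- list()

  truth <- NULL
  em <- NULL
  run_stage("input", {
    if (!is.null(config$sim)) {
      simres <- simulate_expression(config$sim)
      em <- simres$matrix
      truth <- simres$truth
      pc <- simulate_pathways(config$sim, truth)
      dg <- simulate_disease_genes(truth, config$sim$frac_disease_genes,
                                   config$sim$seed + 2L)
      config$pathways <- pc
      config$disease_genes <- dg
      outputs$expression <- write_expression(em, file.path(od, "expression.tsv"))
      outputs$truth <- write_truth(truth, file.path(od, "truth.tsv"))
      outputs$pathways <- write_gmt(pc, file.path(od, "pathways.gmt"))
      outputs$disease_genes <- write_gene_list(dg, file.path(od, "disease_genes.txt"))
    } else {
      if (!is.null(config$expression_path)) em <- read_expression(config$expression_path)
      if (!is.null(config$pathways_path)) config$pathways <- read_gmt(config$pathways_path)
      if (!is.null(config$disease_genes_path)) {
        config$disease_genes <- read_gene_list(config$disease_genes_path)
      }
    }
  }, od)

  degs <- run_stage("deg", {
    if (!is.null(config$deg_table)) {
      d <- config$deg_table
      if (!inherits(d, "deg_table")) {
        d <- screen_degs(stats::setNames(d$ratio, d$gene_id), NULL, config$screen)
      }
      d
    } else {
      run_deg_screen(em, config$screen)
    }
  }, od)
  outputs$degs <- write_deg_table(degs, file.path(od, "degs.tsv"))
  headline$n_genes <- nrow(degs)
  headline$n_up <- sum(degs$call == "up")
  headline$n_down <- sum(degs$call == "down")

  lgn <- run_stage("lgn", {
    disease <- config$disease_genes
    if (is.null(disease)) disease <- degs$gene_id   # no list: every DEG qualifies
    dd <- map_disease_genes(degs, disease)
    headline$n_disease_up <- sum(dd$call == "up")
    headline$n_disease_down <- sum(dd$call == "down")
    build_lgn(dd, config$pathways, disease_genes = disease,
              include_neighbor_genes = config$include_neighbor_genes,
              links = config$links)
  }, od)
  outputs$lgn <- write_lgn(lgn, file.path(od, "lgn_edges.tsv"))[1L]
  comp <- decompose_lgn(lgn)
  headline$n_components <- length(comp$components)
  headline$main_component_size <- length(comp$main)
  headline$n_isolated_pathways <- length(comp$isolated_pathways)

  topo <- run_stage("topology", {
    if (igraph::vcount(lgn) > 0L) topology_summary(lgn) else NULL
  }, od)
  if (!is.null(topo)) {
    outputs$topology <- write_topology(topo, file.path(od, "topology.json"))
    headline$average_degree <- topo$full$average_degree
    headline$average_path_length <- topo$full$average_path_length
    headline$clustering_coefficient <- topo$full$clustering_coefficient
  }

  modules <- run_stage("modules", {
    lapply(config$modules, function(genes) {
      profile_module(genes, degs, config$screen)
    })
  }, od)
  if (length(modules)) {
    headline$modules <- lapply(seq_along(modules), function(i) {
      c(list(name = names(config$modules)[i]), modules[[i]]$summary)
    })
    outputs$modules <- file.path(od, "modules.json")
    jsonlite::write_json(headline$modules, outputs$modules,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  manifest <- list(config_hash = config_fingerprint(config),
                   seed = if (!is.null(config$sim)) config$sim$seed else config$screen$seed,
                   outputs = outputs,
                   headline = headline)
  jsonlite::write_json(manifest, file.path(od, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}

#' Demo run configuration built from the packaged study tables
#'
#' Uses the published 17-gene ratio table as the screened input (the
#' Q-value gate waived, as the table prints ratios only), the union of the
#' packaged table symbols as disease gene set, and a small deterministic
#' synthetic pathway annotation over those genes, so the full pipeline can
#' run end-to-end from the shipped fixtures alone.
#'
#' @param out_dir output directory.
#' @param seed integer seed for the synthetic annotation.
#' @return a [run_config()].
#' @export
demo_run_config <- function(out_dir, seed = 1L) {
  t2 <- load_fixture("table2")
  t3 <- load_fixture("table3")
  t4 <- load_fixture("table4")
  all_genes <- unique(c(t2$symbol, t3$symbol, t4$symbol))
  status <- rep("null", length(all_genes))
  status[match(t2$symbol, all_genes)] <- ifelse(t2$ratio > 1, "up", "down")
  fc <- rep(1, length(all_genes))
  fc[match(t2$symbol, all_genes)] <- t2$ratio
  truth <- data.frame(gene_id = all_genes, true_status = status, true_fc = fc,
                      stringsAsFactors = FALSE)
  cfg <- simulation_config(n_genes = length(all_genes), n_pathways = 10L,
                           pathway_size_range = c(3L, 8L), seed = seed)
  pc <- simulate_pathways(cfg, truth)
  run_config(out_dir,
             screen = screen_params(seed = seed),
             deg_table = screen_degs(stats::setNames(t2$ratio, t2$symbol)),
             pathways = pc,
             disease_genes = all_genes,
             include_neighbor_genes = TRUE,
             modules = list(glucose_metabolism = t3$symbol,
                            lipid_metabolism = t4$symbol))
}
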