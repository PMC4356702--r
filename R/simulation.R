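#' Configuration for the two-group expression simulator
#'
#' The generator emulates the study design downstream stages assume: two
#' conditions ("CK" untreated diabetic control, "RS" resistant-starch
#' treated) with a small number of biological replicates each, log2-normal
#' summarized intensities, and a planted fraction of differentially
#' expressed genes at fixed linear fold changes in both directions.
#' Treatment effects are applied to the RS group only, so a planted ratio
#' above 1 means "up-regulated by RS treatment".
#'
#' Defaults reflect the study conditions the pipeline is screened under:
#' 4 replicates per group, ~5% of genes planted up at fold change 2.5 and
#' ~5% down at 0.4, replicate noise of 0.25 on the log2 scale, baseline
#' intensities centred at 2^7 with SD 1.5 log2 units (typical of
#' RMA-summarized arrays), and a 38-pathway annotation with set sizes 3-15.
#'
#' @param n_genes number of genes.
#' @param n_per_group biological replicates per condition.
#' @param frac_up,frac_down fractions of genes planted up-/down-regulated;
#'   their sum must be `< 1`.
#' @param fc_up linear fold change of planted up genes (`> 1`).
#' @param fc_down linear fold change of planted down genes (in `(0, 1)`).
#' @param noise_sd_log2 replicate noise SD on the log2 scale (`>= 0`).
#' @param baseline_log2_mean,baseline_log2_sd per-gene baseline intensity
#'   distribution, log2 scale.
#' @param seed integer seed governing every stochastic draw.
#' @param n_pathways number of simulated pathway gene sets.
#' @param pathway_size_range inclusive integer interval of set sizes.
#' @param frac_disease_genes fraction of genes placed on the simulated
#'   disease-associated list.
#' @return a validated list of class `"simulation_config"`.
#' @seealso [simulate_expression()], [simulate_pathways()],
#'   [simulate_disease_genes()]
#' @export
simulation_config <- function(n_genes = 1000L,
                              n_per_group = 4L,
                              frac_up = 0.05,
                              frac_down = 0.05,
                              fc_up = 2.5,
                              fc_down = 0.4,
                              noise_sd_log2 = 0.25,
                              baseline_log2_mean = 7,
                              baseline_log2_sd = 1.5,
                              seed = 1L,
                              n_pathways = 38L,
                              pathway_size_range = c(3L, 15L),
                              frac_disease_genes = 0.05) {
  cfg <- list(
    n_genes = check_count(n_genes, "n_genes"),
    n_per_group = check_count(n_per_group, "n_per_group"),
    frac_up = check_fraction(frac_up, "frac_up"),
    frac_down = check_fraction(frac_down, "frac_down"),
    fc_up = fc_up,
    fc_down = fc_down,
    noise_sd_log2 = noise_sd_log2,
    baseline_log2_mean = baseline_log2_mean,
    baseline_log2_sd = baseline_log2_sd,
    seed = check_count(seed, "seed", min = 0L),
    n_pathways = check_count(n_pathways, "n_pathways"),
    pathway_size_range = pathway_size_range,
    frac_disease_genes = check_fraction(frac_disease_genes, "frac_disease_genes", lower_open = TRUE)
  )
  if (cfg$frac_up + cfg$frac_down >= 1) {
    config_error("`frac_up` + `frac_down` must be < 1")
  }
  if (!is.numeric(fc_up) || length(fc_up) != 1L || !is.finite(fc_up) || fc_up <= 1) {
    config_error("`fc_up` must be a single finite number > 1")
  }
  if (!is.numeric(fc_down) || length(fc_down) != 1L || !is.finite(fc_down) ||
      fc_down <= 0 || fc_down >= 1) {
    config_error("`fc_down` must be a single number in (0, 1)")
  }
  if (!is.numeric(noise_sd_log2) || length(noise_sd_log2) != 1L ||
      !is.finite(noise_sd_log2) || noise_sd_log2 < 0) {
    config_error("`noise_sd_log2` must be a single number >= 0")
  }
  if (!is.numeric(baseline_log2_sd) || baseline_log2_sd < 0) {
    config_error("`baseline_log2_sd` must be >= 0")
  }
  if (length(pathway_size_range) != 2L || any(pathway_size_range != trunc(pathway_size_range)) ||
      pathway_size_range[1L] < 1L || pathway_size_range[2L] < pathway_size_range[1L]) {
    config_error("`pathway_size_range` must be an increasing pair of positive integers")
  }
  if (pathway_size_range[2L] > cfg$n_genes) {
    config_error("`pathway_size_range` upper bound exceeds `n_genes`")
  }
  cfg$pathway_size_range <- as.integer(pathway_size_range)
  class(cfg) <- "simulation_config"
  cfg
}

#' Simulate a two-group expression matrix with planted effects
#'
#' Intensities are generated as `2^(baseline + noise)` — with
#' `baseline ~ N(baseline_log2_mean, baseline_log2_sd)` per gene and
#' `noise ~ N(0, noise_sd_log2)` per gene and replicate — and the planted
#' fold change is applied multiplicatively to the RS samples, so the
#' expected RS/CK ratio of a planted gene equals its `true_fc` (and equals
#' it exactly in the noiseless limit). The number of planted
#' up/down genes is `round(frac * n_genes)` each, drawn uniformly without
#' replacement. Identical config (including seed) gives identical output.
#'
#' @param config a [simulation_config()].
#' @return list with components `matrix` (an [expression_matrix()] with
#'   samples `CK_1..CK_n, RS_1..RS_n`) and `truth` (data.frame
#'   `gene_id`, `true_status` in up/down/null, `true_fc`; one row per gene,
#'   `true_fc == 1` exactly for null genes).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_genes
  k <- config$n_per_group
  gene_ids <- sprintf("g%0*d", nchar(n), seq_len(n))
  with_seed(config$seed, {
    n_up <- round(config$frac_up * n)
    n_down <- round(config$frac_down * n)
    de <- sample.int(n, n_up + n_down)
    up <- de[seq_len(n_up)]
    down <- de[n_up + seq_len(n_down)]
    status <- rep("null", n)
    status[up] <- "up"
    status[down] <- "down"
    true_fc <- rep(1, n)
    true_fc[up] <- config$fc_up
    true_fc[down] <- config$fc_down

    baseline <- stats::rnorm(n, config$baseline_log2_mean, config$baseline_log2_sd)
    log2m <- matrix(baseline, nrow = n, ncol = 2L * k)
    if (config$noise_sd_log2 > 0) {
      log2m <- log2m + matrix(stats::rnorm(n * 2L * k, 0, config$noise_sd_log2),
                              nrow = n)
    }
    values <- 2^log2m
    # treatment effect applied multiplicatively on the linear scale; for
    # fold changes that are powers of two (the screen's 2 and 0.5 bounds)
    # the noiseless sample ratio is then exactly the planted value
    rs_cols <- k + seq_len(k)
    values[, rs_cols] <- values[, rs_cols] * true_fc
    dimnames(values) <- list(gene_ids,
                             c(sprintf("CK_%d", seq_len(k)), sprintf("RS_%d", seq_len(k))))
    em <- expression_matrix(values, rep(c("CK", "RS"), each = k))
    truth <- data.frame(gene_id = gene_ids, true_status = status,
                        true_fc = true_fc, stringsAsFactors = FALSE)
    list(matrix = em, truth = truth)
  })
}

#' Simulate pathway gene sets covering all planted DE genes
#'
#' Draws `n_pathways` set sizes uniformly from `pathway_size_range`, places
#' every differentially expressed gene of the truth table into at least one
#' set (round-robin over free slots in random order), and fills the
#' remaining slots with genes sampled at random without within-set
#' duplicates. Stands in for a curated pathway annotation.
#'
#' @param config a [simulation_config()].
#' @param truth truth table from [simulate_expression()].
#' @return a [pathway_collection()] with ids `P01`, `P02`, ...
#' @export
simulate_pathways <- function(config, truth) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.data.frame(truth) || nrow(truth) == 0L) {
    input_error("`truth` must be a nonempty truth table")
  }
  lo <- config$pathway_size_range[1L]
  hi <- config$pathway_size_range[2L]
  np <- config$n_pathways
  genes <- truth$gene_id
  de <- genes[truth$true_status != "null"]
  with_seed(config$seed + 1L, {
    sizes <- lo + sample.int(hi - lo + 1L, np, replace = TRUE) - 1L
    if (length(de) > sum(sizes)) {
      config_error("pathway capacity too small to cover all DE genes; increase n_pathways or pathway_size_range")
    }
    members <- vector("list", np)
    # seed DE genes across pathways in random order, one slot each
    slots <- rep(seq_len(np), sizes)
    slots <- sample(slots)
    for (i in seq_along(de)) {
      p <- slots[i]
      members[[p]] <- c(members[[p]], de[i])
    }
    for (p in seq_len(np)) {
      need <- sizes[p] - length(members[[p]])
      pool <- setdiff(genes, members[[p]])
      members[[p]] <- sample(c(members[[p]], sample(pool, need)))
    }
    names(members) <- sprintf("P%02d", seq_len(np))
    pathway_collection(members,
                       pathway_names = sprintf("simulated pathway %d", seq_len(np)))
  })
}

#' Simulate a disease-associated gene list
#'
#' Samples `ceiling(frac * n_genes)` distinct symbols from the simulated
#' genome; whenever possible the draw is adjusted to contain at least one
#' differentially expressed and one null gene, so downstream disease-gene
#' mapping always has both cases to work with. Stands in for a disease-gene
#' query against a genome database.
#'
#' @param truth truth table from [simulate_expression()].
#' @param frac fraction of genes to select, in `(0, 1]`.
#' @param seed integer seed.
#' @return character vector of gene symbols (a disease gene set).
#' @export
simulate_disease_genes <- function(truth, frac, seed) {
  if (!is.data.frame(truth) || nrow(truth) == 0L) {
    input_error("`truth` must be a nonempty truth table")
  }
  frac <- check_fraction(frac, "frac", lower_open = TRUE)
  n <- nrow(truth)
  m <- as.integer(ceiling(frac * n))
  with_seed(seed, {
    pick <- sample(truth$gene_id, m)
    is_de <- truth$true_status[match(pick, truth$gene_id)] != "null"
    de_all <- truth$gene_id[truth$true_status != "null"]
    null_all <- truth$gene_id[truth$true_status == "null"]
    if (m >= 2L) {
      if (!any(is_de) && length(de_all) > 0L) {
        pick[1L] <- sample(de_all, 1L)
      }
      is_de <- truth$true_status[match(pick, truth$gene_id)] != "null"
      if (all(is_de) && length(null_all) > 0L) {
        pick[which(is_de)[1L]] <- sample(null_all, 1L)
      }
    }
    sort(unique(pick))
  })
}
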