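#' Screening parameters for the differential-expression gate
#'
#' The compound screen used throughout: a gene is called up-regulated when
#' its linear RS/CK ratio is `>= fc_up` and its permutation Q-value is
#' `<= q_max`; down-regulated when the ratio is `<= fc_down` under the same
#' Q gate. Thresholds are applied inclusively, exactly as printed in the
#' study (`ratio >= 2` or `<= 0.5`, `Q <= 5%`).
#'
#' @param fc_up upper fold-change bound (`> 1`), default 2.
#' @param fc_down lower fold-change bound (in `(0, 1)`), default 0.5.
#' @param q_max Q-value gate (in `(0, 1)`), default 0.05.
#' @param n_permutations number of group-label permutations for the
#'   Q-value estimate, default 1000. When the number of distinct label
#'   assignments is no larger, exhaustive enumeration is used instead.
#' @param s0_quantiles candidate percentiles (as probabilities) of the
#'   per-gene standard-error distribution searched by [estimate_s0()].
#' @param pi0 null-gene proportion used in the FDR estimate: the
#'   conservative fixed value 1 (default), or `"estimate"` for the
#'   quartile-based plug-in estimator.
#' @param seed integer seed for permutation sampling.
#' @return a list of class `"screen_params"`.
#' @export
screen_params <- function(fc_up = 2, fc_down = 0.5, q_max = 0.05,
                          n_permutations = 1000L,
                          s0_quantiles = seq(0, 0.95, by = 0.05),
                          pi0 = 1, seed = 1L) {
  if (!is.numeric(fc_up) || fc_up <= 1) config_error("`fc_up` must be > 1")
  if (!is.numeric(fc_down) || fc_down <= 0 || fc_down >= 1) {
    config_error("`fc_down` must be in (0, 1)")
  }
  if (!is.numeric(q_max) || q_max <= 0 || q_max >= 1) {
    config_error("`q_max` must be in (0, 1)")
  }
  n_permutations <- check_count(n_permutations, "n_permutations")
  if (!identical(pi0, "estimate") &&
      (!is.numeric(pi0) || pi0 <= 0 || pi0 > 1)) {
    config_error("`pi0` must be in (0, 1] or \"estimate\"")
  }
  structure(list(fc_up = fc_up, fc_down = fc_down, q_max = q_max,
                 n_permutations = n_permutations,
                 s0_quantiles = s0_quantiles, pi0 = pi0,
                 seed = check_count(seed, "seed", min = 0L)),
            class = "screen_params")
}

#' Per-gene linear fold change
#'
#' `mean(RS intensities) / mean(CK intensities)` on the linear scale, the
#' ratio convention of the study's tables (values above 1 are up-regulated
#' by RS treatment). Swapping the group labels replaces every ratio by its
#' reciprocal.
#'
#' @param em an [expression_matrix()].
#' @return named numeric vector of ratios, one per gene.
#' @export
fold_change <- function(em) {
  stopifnot(inherits(em, "expression_matrix"))
  ck <- group_cols(em, "CK")
  rs <- group_cols(em, "RS")
  if (length(ck) == 0L || length(rs) == 0L) {
    input_error("both groups need at least one sample")
  }
  v <- unclass(em)
  rowMeans(v[, rs, drop = FALSE]) / rowMeans(v[, ck, drop = FALSE])
}

# Per-gene pooled standard error of the RS-CK difference of log2 means:
# s = sqrt((1/n1 + 1/n2) * pooled within-group variance), the two-class
# unpaired, equal-variance form.
pooled_se <- function(log2m, ck, rs) {
  n1 <- length(ck)
  n2 <- length(rs)
  ss1 <- rowSums((log2m[, ck, drop = FALSE] - rowMeans(log2m[, ck, drop = FALSE]))^2)
  ss2 <- rowSums((log2m[, rs, drop = FALSE] - rowMeans(log2m[, rs, drop = FALSE]))^2)
  sqrt((1 / n1 + 1 / n2) * (ss1 + ss2) / (n1 + n2 - 2))
}

#' SAM relative difference (d-statistic)
#'
#' `d = (mean_RS - mean_CK) / (s + s0)` computed on log2 intensities, with
#' `s` the pooled standard error of the difference and `s0` the fudge
#' factor that damps the statistic of low-variance genes. Requires at least
#' two samples per group so the pooled SE is defined; with a single
#' replicate per group, screen on fold change alone instead.
#'
#' @param em an [expression_matrix()].
#' @param s0 nonnegative fudge factor (see [estimate_s0()]).
#' @return named numeric vector of d values.
#' @export
sam_d_statistic <- function(em, s0) {
  stopifnot(inherits(em, "expression_matrix"))
  if (!is.numeric(s0) || length(s0) != 1L || is.na(s0) || s0 < 0) {
    input_error("`s0` must be a single nonnegative number")
  }
  ck <- group_cols(em, "CK")
  rs <- group_cols(em, "RS")
  if (length(ck) < 2L || length(rs) < 2L) {
    input_error("sam_d_statistic needs >= 2 samples per group; use fold-change-only screening otherwise")
  }
  log2m <- log2_values(em)
  d_stat_from_log2(log2m, ck, rs, s0)
}

# Shared kernel so permutations reuse the same code path.
d_stat_from_log2 <- function(log2m, ck, rs, s0) {
  num <- rowMeans(log2m[, rs, drop = FALSE]) - rowMeans(log2m[, ck, drop = FALSE])
  den <- pooled_se(log2m, ck, rs) + s0
  d <- ifelse(den > 0, num / den, 0)
  names(d) <- rownames(log2m)
  d
}

#' Estimate the SAM fudge factor s0
#'
#' Tusher-style grid search: candidates are the percentiles (default 0, 5,
#' ..., 95) of the per-gene pooled-SE distribution; for each candidate the
#' genes are split into up to `n_bins` equal-count SE bins, the spread of d
#' within each bin is summarized by its median absolute deviation, and the
#' candidate minimizing the coefficient of variation of those spreads
#' across bins is chosen (smallest percentile on ties). Deterministic given
#' the matrix. A degenerate all-zero SE distribution returns 0 with a
#' warning.
#'
#' @param em an [expression_matrix()].
#' @param probs candidate percentiles, as probabilities.
#' @param n_bins number of SE bins (reduced when there are few genes).
#' @return scalar `s0 >= 0`.
#' @export
estimate_s0 <- function(em, probs = seq(0, 0.95, by = 0.05), n_bins = 10L) {
  stopifnot(inherits(em, "expression_matrix"))
  ck <- group_cols(em, "CK")
  rs <- group_cols(em, "RS")
  if (length(ck) < 2L || length(rs) < 2L) {
    input_error("estimate_s0 needs >= 2 samples per group")
  }
  log2m <- log2_values(em)
  s <- pooled_se(log2m, ck, rs)
  if (all(s == 0)) {
    warning("all per-gene standard errors are 0; s0 set to 0", call. = FALSE)
    return(0)
  }
  num <- rowMeans(log2m[, rs, drop = FALSE]) - rowMeans(log2m[, ck, drop = FALSE])
  cand <- unname(stats::quantile(s, probs = probs, type = 7))
  n_bins <- max(2L, min(n_bins, floor(length(s) / 2)))
  bins <- cut(rank(s, ties.method = "first"), breaks = n_bins, labels = FALSE)
  cv <- vapply(cand, function(s0) {
    d <- ifelse(s + s0 > 0, num / (s + s0), 0)
    v <- vapply(split(d, bins), stats::mad, numeric(1L))
    if (mean(v) == 0) return(Inf)
    stats::sd(v) / mean(v)
  }, numeric(1L))
  cand[which.min(cv)]   # which.min takes the first (smallest percentile) on ties
}

# All distinct assignments of n1 out of n sample indices to "CK", as a
# matrix with one column per assignment (columns are the CK index sets).
enumerate_assignments <- function(n, n1) {
  utils::combn(n, n1)
}

#' Permutation-based Q-values for the SAM screen
#'
#' For every threshold `t` in the observed `|d|` values the false-discovery
#' rate at `t` is estimated as `pi0 * median_b(#{|d*_b| >= t}) / #{|d| >= t}`,
#' where `d*_b` are the d-statistics recomputed under the b-th permutation
#' of group labels (with `s0` held fixed). A gene's Q-value is the smallest
#' estimated FDR over all thresholds at which the gene is still called
#' (i.e. thresholds `<= |d|` of the gene), clamped to `[0, 1]` — which also
#' makes Q monotone nonincreasing in `|d|`. When the number of distinct
#' group-label assignments is at most `n_permutations` all of them are
#' enumerated; otherwise that many distinct assignments are sampled without
#' replacement under the seed.
#'
#' @param em an [expression_matrix()].
#' @param params a [screen_params()].
#' @param s0 optional fudge factor; estimated from the matrix when NULL.
#' @param method permutation mode: `"auto"` (default; exhaustive when
#'   feasible), `"exhaustive"` or `"sampled"`.
#' @return named numeric vector of Q-values in `[0, 1]`.
#' @export
permutation_q_values <- function(em, params = screen_params(), s0 = NULL,
                                 method = c("auto", "exhaustive", "sampled")) {
  stopifnot(inherits(em, "expression_matrix"), inherits(params, "screen_params"))
  method <- match.arg(method)
  ck <- group_cols(em, "CK")
  rs <- group_cols(em, "RS")
  if (length(ck) < 2L || length(rs) < 2L) {
    input_error("permutation_q_values needs >= 2 samples per group")
  }
  if (is.null(s0)) s0 <- estimate_s0(em)
  log2m <- log2_values(em)
  n <- ncol(log2m)
  n1 <- length(ck)
  d_obs <- d_stat_from_log2(log2m, ck, rs, s0)
  ad <- abs(d_obs)

  n_assign <- choose(n, n1)
  exhaust <- method == "exhaustive" ||
    (method == "auto" && n_assign <= params$n_permutations)
  if (exhaust || n_assign <= 1e5) {
    all_assign <- enumerate_assignments(n, n1)
    if (exhaust) {
      ck_sets <- lapply(seq_len(ncol(all_assign)), function(j) all_assign[, j])
    } else {
      # distinct assignments sampled without replacement
      idx <- with_seed(params$seed,
                       sample.int(ncol(all_assign),
                                  min(params$n_permutations, ncol(all_assign))))
      ck_sets <- lapply(idx, function(j) all_assign[, j])
    }
  } else {
    # design too large to enumerate: independent random label shuffles
    ck_sets <- with_seed(params$seed,
                         replicate(params$n_permutations,
                                   sample.int(n, n1), simplify = FALSE))
  }
  perm_abs <- lapply(ck_sets, function(ckp) {
    rsp <- setdiff(seq_len(n), ckp)
    abs(d_stat_from_log2(log2m, ckp, rsp, s0))
  })

  # counts of |d*| >= t for every observed threshold t, per permutation
  thr <- sort(ad)
  counts_ge <- function(v, t) {
    sv <- sort(v)
    length(sv) - findInterval(t, sv, left.open = TRUE)
  }
  V <- vapply(perm_abs, counts_ge, numeric(length(thr)), t = thr)
  if (is.null(dim(V))) V <- matrix(V, nrow = length(thr))
  med_V <- apply(V, 1L, stats::median)
  obs_O <- counts_ge(ad, thr)

  pi0 <- if (identical(params$pi0, "estimate")) {
    pooled <- unlist(perm_abs, use.names = FALSE)
    qq <- stats::quantile(pooled, c(0.25, 0.75))
    min(1, sum(ad >= qq[1L] & ad <= qq[2L]) / (0.5 * length(ad)))
  } else {
    params$pi0
  }
  fdr_at_thr <- pmin(1, pi0 * med_V / pmax(obs_O, 1L))
  # q at threshold index i = min FDR over thresholds 1..i (all thresholds
  # at which that gene is still called); running min also enforces
  # monotonicity of q in |d|
  q_at_thr <- cummin(fdr_at_thr)
  q <- q_at_thr[findInterval(ad, thr)]   # last index with thr <= |d|; ties safe
  names(q) <- names(d_obs)
  attr(q, "d_stat") <- d_obs
  attr(q, "s0") <- s0
  attr(q, "pi0") <- pi0
  attr(q, "n_permutations_used") <- length(perm_abs)
  attr(q, "exhaustive") <- length(perm_abs) == n_assign
  q
}

#' Apply the compound fold-change / Q-value screen
#'
#' A gene is `up` iff `ratio >= fc_up` and `q <= q_max`; `down` iff
#' `ratio <= fc_down` and `q <= q_max`; otherwise `unchanged`. Bounds are
#' inclusive. When `q_values` is NULL the Q gate is waived (all q set to
#' 0), which screens on fold change alone — the mode used with tables of
#' published ratios.
#'
#' @param ratios named vector of linear fold changes (see [fold_change()]).
#' @param q_values named vector of Q-values over the same genes, or NULL.
#' @param params a [screen_params()].
#' @return a `deg_table` data.frame with columns `gene_id`, `ratio`,
#'   `d_stat`, `q_value`, `call`.
#' @export
screen_degs <- function(ratios, q_values = NULL, params = screen_params()) {
  stopifnot(inherits(params, "screen_params"))
  genes <- names(ratios)
  if (is.null(genes)) input_error("`ratios` must be a named vector")
  d_stat <- rep(NA_real_, length(ratios))
  if (is.null(q_values)) {
    q_values <- stats::setNames(rep(0, length(ratios)), genes)
  } else {
    if (is.null(names(q_values)) || !setequal(names(q_values), genes)) {
      miss <- c(setdiff(genes, names(q_values)), setdiff(names(q_values), genes))
      input_error(sprintf("gene sets of ratios and q_values differ: %s%s",
                          paste(utils::head(miss, 10L), collapse = ", "),
                          if (length(miss) > 10L) ", ..." else ""))
    }
    if (!is.null(attr(q_values, "d_stat"))) {
      d_stat <- unname(attr(q_values, "d_stat")[genes])
    }
    q_values <- q_values[genes]
  }
  call <- ifelse(ratios >= params$fc_up & q_values <= params$q_max, "up",
                 ifelse(ratios <= params$fc_down & q_values <= params$q_max,
                        "down", "unchanged"))
  out <- data.frame(gene_id = genes, ratio = unname(ratios),
                    d_stat = d_stat, q_value = unname(q_values),
                    call = unname(call), stringsAsFactors = FALSE)
  class(out) <- c("deg_table", "data.frame")
  out
}

#' Run the full differential-expression screen on a matrix
#'
#' Convenience composition: fold changes, s0 estimate, d-statistics,
#' permutation Q-values, then the compound screen.
#'
#' @param em an [expression_matrix()].
#' @param params a [screen_params()].
#' @return a `deg_table` (see [screen_degs()]) with attributes `s0` and
#'   `n_permutations_used`.
#' @export
run_deg_screen <- function(em, params = screen_params()) {
  ratios <- fold_change(em)
  q <- permutation_q_values(em, params)
  out <- screen_degs(ratios, q, params)
  attr(out, "s0") <- attr(q, "s0")
  attr(out, "n_permutations_used") <- attr(q, "n_permutations_used")
  out
}

#' Average-linkage hierarchical clustering on correlation distance
#'
#' Agglomerative clustering of genes or samples with distance
#' `1 - Pearson correlation` of log2 profiles and average (UPGMA) linkage —
#' the global expression-pattern assessment behind the study's cluster
#' figure. A zero-variance profile has its correlations defined as 0 (with
#' a warning) so it clusters last rather than erroring.
#'
#' @param em an [expression_matrix()].
#' @param axis `"genes"` or `"samples"`.
#' @return an `hclust` object.
#' @seealso [write_newick()] to export the dendrogram.
#' @export
hierarchical_cluster <- function(em, axis = c("genes", "samples")) {
  axis <- match.arg(axis)
  log2m <- log2_values(em)
  prof <- if (axis == "genes") t(log2m) else log2m
  if (ncol(prof) < 2L) input_error("need >= 2 items to cluster")
  sds <- apply(prof, 2L, stats::sd)
  cc <- suppressWarnings(stats::cor(prof))
  if (any(sds == 0)) {
    warning(sprintf("%d zero-variance profile(s); their correlations set to 0",
                    sum(sds == 0)), call. = FALSE)
  }
  cc[!is.finite(cc)] <- 0
  diag(cc) <- 1
  stats::hclust(stats::as.dist(1 - cc), method = "average")
}

#' Export a dendrogram in Newick format
#' @param hc an `hclust` object (see [hierarchical_cluster()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(hc, path) {
  stopifnot(inherits(hc, "hclust"))
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}
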