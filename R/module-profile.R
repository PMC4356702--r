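#' Profile a metabolism module
#'
#' Attaches expression ratios to an ordered list of metabolism genes ("in
#' the order they appear in the metabolic process") and summarizes the
#' regulation direction. Two distinct notions of "up" are reported to avoid
#' conflation: the figures' criterion (ratio strictly above/below 1) and
#' the screen's compound thresholds (`ratio >= fc_up` or `<= fc_down`).
#' Genes without a measured ratio stay missing — fabricating a neutral 1.0
#' would bias the summary.
#'
#' @param ordered_genes character vector of gene symbols in pathway order;
#'   duplicates (case-insensitive) are an error.
#' @param ratios named numeric vector of linear ratios, or a `deg_table`;
#'   matched to the module by case-insensitive symbol.
#' @param params a [screen_params()] supplying the screen thresholds.
#' @param module_name label for the module.
#' @return list of class `"metabolism_module"`: `module_name`, `genes`
#'   (data.frame `symbol`, `ratio`, `status` in up/down/equal/missing,
#'   `pass_screen`; input order preserved) and `summary` (`n_total`,
#'   `n_with_ratio`, `n_up`, `n_down`, `n_equal`, `n_missing`,
#'   `n_pass_screen`).
#' @examples
#' t2 <- load_fixture("table2")
#' glucose <- load_fixture("table3")
#' profile_module(glucose$symbol, stats::setNames(t2$ratio, t2$symbol),
#'                module_name = "glucose metabolism")$summary
#' @export
profile_module <- function(ordered_genes, ratios, params = screen_params(),
                           module_name = "module") {
  ordered_genes <- as.character(ordered_genes)
  if (length(ordered_genes) == 0L) input_error("`ordered_genes` must be nonempty")
  key <- symbol_key(ordered_genes)
  if (anyDuplicated(key)) {
    input_error(sprintf("duplicate symbol(s) in the ordered gene list: %s",
                        paste(unique(ordered_genes[duplicated(key)]), collapse = ", ")))
  }
  if (inherits(ratios, "deg_table") || is.data.frame(ratios)) {
    ratios <- stats::setNames(ratios$ratio, ratios$gene_id)
  }
  if (is.null(names(ratios))) input_error("`ratios` must be named by gene symbol")
  r <- unname(ratios[match(key, symbol_key(names(ratios)))])
  status <- ifelse(is.na(r), "missing",
                   ifelse(r > 1, "up", ifelse(r < 1, "down", "equal")))
  pass <- !is.na(r) & (r >= params$fc_up | r <= params$fc_down)
  genes <- data.frame(symbol = ordered_genes, ratio = r, status = status,
                      pass_screen = pass, stringsAsFactors = FALSE)
  summary <- list(n_total = length(ordered_genes),
                  n_with_ratio = sum(!is.na(r)),
                  n_up = sum(status == "up"),
                  n_down = sum(status == "down"),
                  n_equal = sum(status == "equal"),
                  n_missing = sum(status == "missing"),
                  n_pass_screen = sum(pass))
  structure(list(module_name = module_name, genes = genes, summary = summary),
            class = "metabolism_module")
}

#' @export
print.metabolism_module <- function(x, ...) {
  s <- x$summary
  cat(sprintf("metabolism_module '%s': %d genes (%d measured: %d up, %d down; %d pass screen)\n",
              x$module_name, s$n_total, s$n_with_ratio, s$n_up, s$n_down,
              s$n_pass_screen))
  invisible(x)
}
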