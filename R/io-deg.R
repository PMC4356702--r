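#' Write a differential-expression table as TSV
#'
#' Fixed column order `gene_id, ratio, d_stat, q_value, call`. Ratios are
#' held at full float precision in memory and printed at 4 decimals,
#' matching the style of the published ratio table; `d_stat` and `q_value`
#' are printed with 6 significant digits. An empty table writes the header
#' only.
#'
#' @param deg a `deg_table` data.frame (see [screen_degs()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_deg_table <- function(deg, path) {
  cols <- c("gene_id", "ratio", "d_stat", "q_value", "call")
  if (!all(cols %in% names(deg))) {
    input_error(sprintf("DEG table must have columns %s", paste(cols, collapse = ", ")))
  }
  out <- deg[cols]
  fmt <- function(x, f) ifelse(is.na(x), "NA", sprintf(f, x))
  lines <- c(paste(cols, collapse = "\t"),
             if (nrow(out) > 0L) paste(out$gene_id,
                                       fmt(out$ratio, "%.4f"),
                                       fmt(out$d_stat, "%.6g"),
                                       fmt(out$q_value, "%.6g"),
                                       out$call, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a differential-expression table written by [write_deg_table()]
#' @param path file path.
#' @return a `deg_table` data.frame.
#' @export
read_deg_table <- function(path) {
  if (!file.exists(path)) format_error(sprintf("DEG table not found: %s", path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  cols <- c("gene_id", "ratio", "d_stat", "q_value", "call")
  if (!identical(names(df), cols)) {
    format_error(sprintf("'%s' must have columns %s", path, paste(cols, collapse = ", ")))
  }
  class(df) <- c("deg_table", "data.frame")
  df
}
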