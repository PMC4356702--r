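#' Read a two-group expression matrix from TSV
#'
#' The dialect is self-contained: row 1 is the header `gene_id` followed by
#' sample ids; row 2 is the literal word `group` followed by the group label
#' (`CK` or `RS`) of each sample; data rows follow, one gene per row with
#' linear-scale intensities. Readers reject rather than repair: duplicated
#' identifiers, non-positive or non-numeric values and unknown group labels
#' are all format errors naming the offender.
#'
#' @param path file path.
#' @return an [expression_matrix()], row order preserved.
#' @seealso [write_expression()]
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) format_error(sprintf("expression file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 3L) {
    format_error(sprintf("'%s' must contain a header row, a group row and >=1 data row", path))
  }
  split_row <- function(x) trimws(strsplit(x, "\t", fixed = TRUE)[[1L]])
  header <- split_row(lines[1L])
  if (tolower(header[1L]) != "gene_id" || length(header) < 2L) {
    format_error(sprintf("'%s': first header field must be 'gene_id' followed by sample ids", path))
  }
  samples <- header[-1L]
  grow <- split_row(lines[2L])
  if (tolower(grow[1L]) != "group" || length(grow) != length(header)) {
    format_error(sprintf("'%s': second row must be 'group' followed by one label per sample", path))
  }
  groups <- grow[-1L]
  n <- length(lines) - 2L
  values <- matrix(NA_real_, nrow = n, ncol = length(samples))
  gene_ids <- character(n)
  for (i in seq_len(n)) {
    fields <- split_row(lines[i + 2L])
    if (length(fields) != length(header)) {
      format_error(sprintf("'%s' row %d: expected %d fields, found %d",
                           path, i + 2L, length(header), length(fields)))
    }
    gene_ids[i] <- fields[1L]
    v <- suppressWarnings(as.numeric(fields[-1L]))
    if (anyNA(v)) {
      j <- which(is.na(v))[1L]
      format_error(sprintf("'%s': non-numeric value for gene '%s', sample '%s'",
                           path, fields[1L], samples[j]))
    }
    values[i, ] <- v
  }
  dimnames(values) <- list(gene_ids, samples)
  expression_matrix(values, stats::setNames(groups, samples))
}

#' Write a two-group expression matrix as TSV
#'
#' Values are printed with 6 significant digits (the package's fixed
#' printing precision for intensities); a write/read round trip is the
#' identity up to that precision.
#'
#' @param em an [expression_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(em, path) {
  stopifnot(inherits(em, "expression_matrix"))
  groups <- attr(em, "groups")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("gene_id", colnames(em)), collapse = "\t"), con)
  writeLines(paste(c("group", groups), collapse = "\t"), con)
  body <- apply(unclass(em), 1L, function(v) paste(sprintf("%.6g", v), collapse = "\t"))
  writeLines(paste(rownames(em), body, sep = "\t"), con)
  invisible(path)
}

#' Write a truth table (planted differential-expression status) as TSV
#' @param truth data.frame with columns `gene_id`, `true_status`, `true_fc`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  stopifnot(all(c("gene_id", "true_status", "true_fc") %in% names(truth)))
  utils::write.table(truth[c("gene_id", "true_status", "true_fc")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
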