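#' Two-group expression matrix
#'
#' The unit of all screening statistics: a genes-by-samples matrix of
#' strictly positive, linear-scale summarized intensities (as produced by
#' RMA followed by back-transformation), with every sample assigned to one
#' of two conditions — `"CK"` (untreated diabetic control) or `"RS"`
#' (resistant-starch treated).
#'
#' @param values numeric matrix, genes in rows and samples in columns, with
#'   unique row and column names. All values must be finite and `> 0`.
#' @param groups character vector assigning each column to `"CK"` or `"RS"`.
#'   Either named by sample or given in column order.
#' @return An object of class `"expression_matrix"`: the validated matrix
#'   with a `groups` attribute (named character vector, sample -> group).
#' @examples
#' m <- matrix(c(100, 120, 220, 220), nrow = 1,
#'             dimnames = list("Gck", c("CK_1", "CK_2", "RS_1", "RS_2")))
#' em <- expression_matrix(m, c("CK", "CK", "RS", "RS"))
#' fold_change(em)
#' @export
expression_matrix <- function(values, groups) {
  if (!is.matrix(values) || !is.numeric(values)) {
    format_error("`values` must be a numeric matrix")
  }
  gid <- rownames(values)
  sid <- colnames(values)
  if (is.null(gid) || is.null(sid)) {
    format_error("`values` must carry gene row names and sample column names")
  }
  dup_g <- gid[duplicated(gid)]
  if (length(dup_g)) {
    format_error(sprintf("duplicated gene identifier(s): %s",
                         paste(unique(dup_g), collapse = ", ")))
  }
  dup_s <- sid[duplicated(sid)]
  if (length(dup_s)) {
    format_error(sprintf("duplicated sample identifier(s): %s",
                         paste(unique(dup_s), collapse = ", ")))
  }
  bad <- which(!is.finite(values) | values <= 0)
  if (length(bad)) {
    i <- arrayInd(bad[1L], dim(values))
    format_error(sprintf(
      "intensities must be finite and > 0; offending value at gene '%s', sample '%s'",
      gid[i[1L]], sid[i[2L]]))
  }
  groups <- as.character(groups)
  if (!is.null(names(groups))) {
    if (!setequal(names(groups), sid)) {
      format_error("names of `groups` must match the sample identifiers")
    }
    groups <- groups[sid]
  } else if (length(groups) == ncol(values)) {
    names(groups) <- sid
  } else {
    format_error("`groups` must have one entry per sample")
  }
  unknown <- setdiff(unique(groups), c("CK", "RS"))
  if (length(unknown)) {
    format_error(sprintf("unknown group label(s): %s (expected CK or RS)",
                         paste(unknown, collapse = ", ")))
  }
  if (!all(c("CK", "RS") %in% groups)) {
    format_error("both groups CK and RS must be nonempty")
  }
  structure(values, groups = groups, class = c("expression_matrix", "matrix", "array"))
}

#' @export
print.expression_matrix <- function(x, ...) {
  g <- attr(x, "groups")
  cat(sprintf("expression_matrix: %d genes x %d samples (CK: %d, RS: %d)\n",
              nrow(x), ncol(x), sum(g == "CK"), sum(g == "RS")))
  invisible(x)
}

# Column indices of one group.
group_cols <- function(em, group) {
  which(attr(em, "groups") == group)
}

# log2 intensities as a plain matrix (drops the class).
log2_values <- function(em) {
  v <- log2(unclass(em))
  attr(v, "groups") <- NULL
  v
}

#' @export
`[.expression_matrix` <- function(x, i, j, ..., drop = FALSE) {
  g <- attr(x, "groups")
  v <- unclass(x)
  attr(v, "groups") <- NULL
  out <- v[i, j, drop = FALSE]
  if (!missing(j)) g <- g[j]
  expression_matrix(out, g)
}
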