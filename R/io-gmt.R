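#' Pathway collection
#'
#' Ordered, named gene sets — the knowledge base used to assemble the local
#' gene network. Backed by the GMT format on disk.
#'
#' @param members named list of character vectors (member gene symbols);
#'   names are the pathway ids, which must be unique. Member lists must be
#'   nonempty and free of duplicates.
#' @param pathway_names optional character vector of human-readable names,
#'   one per pathway (GMT "description" column).
#' @return list of class `"pathway_collection"` with a `pathway_names`
#'   attribute.
#' @export
pathway_collection <- function(members, pathway_names = NULL) {
  if (!is.list(members) || length(members) == 0L || is.null(names(members)) ||
      any(!nzchar(names(members)))) {
    format_error("`members` must be a nonempty named list of gene-symbol vectors")
  }
  ids <- names(members)
  if (anyDuplicated(ids)) {
    format_error(sprintf("duplicated pathway id(s): %s",
                         paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  for (i in seq_along(members)) {
    m <- as.character(members[[i]])
    if (length(m) == 0L) {
      format_error(sprintf("pathway '%s' has no members", ids[i]))
    }
    if (anyDuplicated(m)) {
      format_error(sprintf("pathway '%s' lists duplicate members", ids[i]))
    }
    members[[i]] <- m
  }
  if (is.null(pathway_names)) {
    pathway_names <- ids
  }
  if (length(pathway_names) != length(members)) {
    format_error("`pathway_names` must have one entry per pathway")
  }
  structure(members, pathway_names = stats::setNames(as.character(pathway_names), ids),
            class = "pathway_collection")
}

#' @export
print.pathway_collection <- function(x, ...) {
  sizes <- lengths(x)
  cat(sprintf("pathway_collection: %d gene sets (sizes %d-%d)\n",
              length(x), min(sizes), max(sizes)))
  invisible(x)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one pathway per line, tab-separated fields
#' `id<TAB>description<TAB>member1<TAB>member2...`, at least three fields.
#' Blank lines are skipped; a duplicated member within one line is dropped
#' with a warning (the only repair a reader performs — every other
#' structural violation is an error).
#'
#' @param path file path.
#' @return a [pathway_collection()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) format_error(sprintf("GMT file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  members <- list()
  pnames <- character()
  for (ln in keep) {
    fields <- strsplit(lines[ln], "\t", fixed = TRUE)[[1L]]
    fields <- trimws(fields)
    fields <- fields[nzchar(fields) | seq_along(fields) <= 2L]
    if (length(fields) < 3L) {
      format_error(sprintf("line %d of '%s' has fewer than 3 tab-separated fields",
                           ln, path))
    }
    id <- fields[1L]
    mem <- fields[-(1:2)]
    if (anyDuplicated(mem)) {
      warning(sprintf("pathway '%s' (line %d): duplicate members dropped", id, ln),
              call. = FALSE)
      mem <- unique(mem)
    }
    members[[id]] <- mem
    pnames <- c(pnames, fields[2L])
  }
  pathway_collection(members, pathway_names = pnames)
}

#' Write gene sets to a GMT file
#'
#' @param pathways a [pathway_collection()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(pathways, path) {
  stopifnot(inherits(pathways, "pathway_collection"))
  pn <- attr(pathways, "pathway_names")
  lines <- vapply(seq_along(pathways), function(i) {
    paste(c(names(pathways)[i], pn[[i]], pathways[[i]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read a disease-associated gene list
#'
#' One symbol per line; blank lines and `#` comments are skipped. The file
#' stands in for a disease-gene query against a genome database.
#'
#' @param path file path.
#' @return character vector of unique symbols.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) format_error(sprintf("gene list not found: %s", path))
  x <- trimws(readLines(path, warn = FALSE))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  if (length(x) == 0L) format_error(sprintf("gene list '%s' is empty", path))
  unique(x)
}

#' Write a gene list, one symbol per line
#' @param genes character vector of symbols.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(as.character(genes), path)
  invisible(path)
}
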