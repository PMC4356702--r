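#' Packaged study tables
#'
#' Small plain-text fixtures transcribed from the published study tables,
#' shipped with the package so the headline analyses can be re-run without
#' any external download:
#'
#' * `"table2"` — the 17 diabetes-associated genes differentially expressed
#'   in liver after resistant-starch treatment, with gene name and linear
#'   RS/CK expression ratio (data.frame `symbol`, `name`, `ratio`).
#' * `"table3"` — the 13 glucose-metabolism genes of the local gene
#'   network, ordered by their position in the metabolic process
#'   (data.frame `symbol`, `name`).
#' * `"table4"` — the 12 lipid-metabolism genes, same ordering convention.
#'   The printed symbol `Cptla` is preserved exactly as published; an
#'   `aliases` attribute records it as a probable transcription variant of
#'   `Cpt1a` (`table2`) without asserting identity.
#' * `"forkhead_links"` — the published pathway-link list of the forkhead
#'   class A signaling pathway (`R1`), an edge list connecting it to eight
#'   other pathways (data.frame `from`, `to`, `to_name`).
#'
#' @param name one of `"table2"`, `"table3"`, `"table4"`,
#'   `"forkhead_links"`.
#' @return a data.frame as described above.
#' @examples
#' t2 <- load_fixture("table2")
#' nrow(t2)                       # 17 genes
#' t2$ratio[t2$symbol == "Gck"]   # 0.3975, down-regulated
#' @export
load_fixture <- function(name) {
  files <- c(table2 = "table2.tsv", table3 = "table3.tsv",
             table4 = "table4.tsv", forkhead_links = "forkhead_links.tsv")
  if (length(name) != 1L || !name %in% names(files)) {
    input_error(sprintf("unknown fixture '%s'; expected one of %s",
                        paste(name, collapse = ","),
                        paste(names(files), collapse = ", ")))
  }
  path <- system.file("extdata", files[[name]], package = "rslgn", mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (name == "table4") {
    attr(df, "aliases") <- data.frame(printed = "Cptla", probable = "Cpt1a",
                                      stringsAsFactors = FALSE)
  }
  df
}
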