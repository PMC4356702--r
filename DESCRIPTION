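Package: rslgn
Title: Local Gene Network Analysis of Liver Transcriptomes Under
    Resistant-Starch Treatment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for the transcriptome analysis of
    resistant-starch-treated diabetic rat liver: SAM-style (significance
    analysis of microarrays) differential-expression screening with
    permutation Q-values and a compound fold-change gate, mapping of
    screened genes onto a disease-associated gene list, assembly of a
    Local Gene Network (LGN) that links disease-associated regulated
    genes through shared pathway annotations, graph-topology
    characterization (degrees, path length, clustering coefficient,
    component structure, scale-free diagnostics), and metabolism-module
    ratio profiling.  A seeded synthetic-data generator produces
    two-group expression matrices with planted differential expression
    and matching pathway and disease-gene annotations, so every stage is
    testable against known ground truth without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
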