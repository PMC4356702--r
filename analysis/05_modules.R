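#!/usr/bin/env Rscript

# Stage 5 — metabolism-module profiles.
#
# Joins the published 17-gene ratio table to the glucose- and
# lipid-metabolism gene orderings (genes listed by their position in the
# metabolic process) and summarizes regulation direction under both
# criteria: ratio > 1 ("up with RS treatment", the figures' reading) and
# the screen's ratio >= 2 / <= 0.5 gate.

suppressPackageStartupMessages(library(rslgn))

out <- "results/modules"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

t2 <- load_fixture("table2")
ratios <- stats::setNames(t2$ratio, t2$symbol)

mods <- list(glucose_metabolism = load_fixture("table3")$symbol,
             lipid_metabolism = load_fixture("table4")$symbol)
report <- lapply(names(mods), function(nm) {
  m <- profile_module(mods[[nm]], ratios, module_name = nm)
  print(m)
  measured <- m$genes[!is.na(m$genes$ratio), ]
  cat(sprintf("  measured: %s\n",
              paste(sprintf("%s=%.4f", measured$symbol, measured$ratio),
                    collapse = ", ")))
  c(list(module = nm), m$summary)
})
jsonlite::write_json(report, file.path(out, "module_profiles.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat(sprintf("module report written to %s\n",
            file.path(out, "module_profiles.json")))
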