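#!/usr/bin/env Rscript
# Stage 3: gene-tree topology classification.
#
# Each family phylogeny is rooted on the hytrosavirus outgroup and its
# supported (UFboot > 80) wasp-only clades are typed by their nearest
# viral relative: type I (ancestral, LhFV-adjacent, all wasp tips in one
# clade), type II (single-species LbFV-adjacent), type III (both).

suppressPackageStartupMessages(library(waspEVE))

calls <- run_classify("scratch/analysis_dataset", out_dir = "results")
types <- vapply(calls, `[[`, character(1), "type")
print(table(types))
cat("unclassified families:",
    paste(names(types)[types == "UNCLASSIFIED"], collapse = ", "), "\n")
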