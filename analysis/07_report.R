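#!/usr/bin/env Rscript
# Stage 7: final report.
#
# Species x family presence/absence matrix with per-cell annotations
# (copy number; '*' all copies degraded, '(*)' some; '#' alternative
# start codon), plus the combined report written by the earlier stages.

suppressPackageStartupMessages(library(waspEVE))

m <- run_report("scratch/analysis_dataset", out_dir = "results")
cat(sprintf("presence matrix: %d species x %d families -> results/presence_matrix.tsv\n",
            nrow(m), ncol(m)))
sub <- m[, intersect(colnames(m), c("lef-5", "orf10", "orf11", "odv-e66",
                                    "orf85", "integrase")), drop = FALSE]
print(sub, quote = FALSE)
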