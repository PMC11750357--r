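#!/usr/bin/env Rscript
# Stage 2: EVE detection and chromosomal-integration evidence.
#
# Filters viral homology hits (e-value <= 1e-3), merges overlapping
# same-strand hits into loci, calls ORF integrity, and scores every
# EVE-candidate scaffold against its species' BUSCO GC/coverage envelope
# plus eukaryotic-gene / TE evidence.

suppressPackageStartupMessages(library(waspEVE))

det <- run_detect("scratch/analysis_dataset", out_dir = "results")

cat(sprintf("catalog: %d EVE loci on %d scaffolds\n",
            nrow(det$catalog), length(unique(det$catalog$scaffold))))
print(table(det$catalog$orf_status))
cat("integration verdicts:\n")
print(table(det$evidence$verdict))
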