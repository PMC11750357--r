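#!/usr/bin/env Rscript
# Stage 1: generate the study-mimic synthetic dataset.
#
# Two planted endogenization events over six EVE-positive cynipoid wasps
# (ancestral: 18 families from an LhFV-like donor at the crown of the six;
# recent: 9 families from an LbFV-like donor on the Rhoptromeris branch,
# 16 copies, 7 degraded), 5 families shared, plus 3 orphan loci. The raw
# dataset (scaffold FASTAs, hit tables, trees, alignments) lands under
# scratch/; the truth tables are copied to results/ for the later stages'
# comparisons.

suppressPackageStartupMessages(library(waspEVE))

data_dir <- "scratch/analysis_dataset"
dir.create("results", showWarnings = FALSE)

ds <- run_simulate("study-mimic", data_dir)
print(ds)

invisible(file.copy(file.path(data_dir, "truth",
                    c("truth_loci.tsv", "truth_families.tsv",
                      "truth_events.tsv")),
          "results", overwrite = TRUE))

cat(sprintf("planted: %d loci across %d positive species; %d families\n",
            nrow(ds$truth_loci), length(unique(ds$truth_loci$species)),
            nrow(ds$truth_families)))
print(ds$truth_events[, c("event_id", "donor_lineage", "n_loci",
                          "n_families")])
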