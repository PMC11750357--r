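#!/usr/bin/env Rscript
# Stage 4: event assignment by transitive colocation + shared clades.
#
# Colocation edges join loci on one scaffold; homology-clade edges join
# same-family loci sitting in the same supported wasp clade. Connected
# components (union-find) are the endogenization events.

suppressPackageStartupMessages(library(waspEVE))

grouped <- run_assign("scratch/analysis_dataset", out_dir = "results")
for (ev in grouped$events)
  cat(sprintf("%s: %d loci, %d families, species = %s, donor = %s%s\n",
              ev$event_id, ev$n_loci, length(ev$families),
              paste(ev$species, collapse = ","), ev$donor_lineage,
              if (ev$conflict) " [donor conflict]" else ""))
cat("unassigned loci:", length(grouped$unassigned), "\n")
if (length(grouped$events) == 2) {
  shared <- intersect(grouped$events[[1]]$families,
                      grouped$events[[2]]$families)
  cat("families shared between the two events:", length(shared), "\n")
}
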