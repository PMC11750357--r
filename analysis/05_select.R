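#!/usr/bin/env Rscript
# Stage 5: selection analysis.
#
# Nei-Gojobori dN/dS per family over all sequence pairs, a regime call
# (purifying / neutral / undetermined) from a t test of pairwise omegas
# against 1, and a pooled-variance comparison of EVE vs BUSCO-gene
# pairwise omegas.

suppressPackageStartupMessages(library(waspEVE))

sel <- run_select("scratch/analysis_dataset", out_dir = "results")
print(table(sel$omega_table$regime))
ot <- sel$omega_table
cat("families with omega not distinguishable from 1:\n")
print(ot[ot$regime == "neutral", c("family", "mean_omega", "se_omega")])
cmp <- sel$comparison
cat(sprintf("EVE vs BUSCO pairwise omega: %.4f vs %.4f (t = %.2f, df = %d, p = %.3g)\n",
            cmp$mean_eve, cmp$mean_busco, cmp$t, cmp$df, cmp$p))
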