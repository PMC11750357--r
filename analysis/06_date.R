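#!/usr/bin/env Rscript
# Stage 6: enrichment and dating.
#
# Core-gene enrichment of each event's families against its donor virus
# repertoire (Fisher exact, conditional-MLE odds ratio), and event dating
# on the calibrated chronogram: crown age of the recipient clade as lower
# bound, split from the closest EVE-negative relative as upper bound.

suppressPackageStartupMessages(library(waspEVE))

dated <- run_date("scratch/analysis_dataset", out_dir = "results")
for (d in dated)
  cat(sprintf("%s (%d species): %.1f - %.1f Myr%s\n", d$event_id,
              length(d$species), d$lower_age, d$upper_age,
              if (!is.null(d$lower_ci))
                sprintf(" (crown CI %.0f-%.0f)", d$lower_ci[1], d$lower_ci[2])
              else if (!is.null(d$upper_ci))
                sprintf(" (split CI %.0f-%.0f)", d$upper_ci[1], d$upper_ci[2])
              else "")

  )

# enrichment for the ancestral event (also part of report.json in run_all)
panel <- read.table("scratch/analysis_dataset/virus_panel.tsv", sep = "\t",
                    header = TRUE, comment.char = "#")
events <- jsonlite::read_json("results/events.json",
                              simplifyVector = TRUE,
                              simplifyDataFrame = FALSE)$events
for (ev in events) {
  donor <- unique(panel$virus[panel$lineage == ev$donor_lineage])[1]
  rep_df <- panel[panel$virus == donor, c("family", "core")]
  enr <- core_gene_enrichment(unlist(ev$families), rep_df)
  cat(sprintf("%s vs %s: %d/%d core vs %d/%d; OR = %.2f, p = %.4g\n",
              ev$event_id, donor, enr$n_event_core, enr$n_event,
              enr$n_donor_core, enr$n_donor, enr$odds_ratio, enr$p))
}
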