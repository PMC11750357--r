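# Shared fixtures: the study-mimic dataset and its full pipeline run are
# generated once per test session and cached.

.fixture_env <- new.env(parent = emptyenv())

mimic_fixture <- function() {
  if (is.null(.fixture_env$mimic)) {
    dir <- file.path(tempdir(), "waspEVE-mimic-fixture")
    ds <- run_simulate("study-mimic", dir)
    res <- run_all(dir)
    .fixture_env$mimic <- list(dir = dir, ds = ds, res = res)
  }
  .fixture_env$mimic
}

# A small tip-metadata table for hand-built trees: tips W* are wasp
# (species from suffix or sp1), V*/LhFV*/LbFV*/OG* are viruses.
toy_metadata <- function(tips) {
  kind <- ifelse(grepl("^W", tips), "wasp", "virus")
  lineage <- rep("", length(tips))
  lineage[grepl("^LhFV", tips)] <- "LhFV-like"
  lineage[grepl("^LbFV", tips)] <- "LbFV-like"
  lineage[grepl("^V", tips)] <- "other-FV"
  lineage[grepl("^OG", tips)] <- "outgroup"
  species <- tips
  species[kind == "wasp"] <- sub("^(W[a-z]*)[0-9]*$", "\\1", tips[kind == "wasp"])
  data.frame(tip = tips, kind = kind, species = species, lineage = lineage,
             stringsAsFactors = FALSE)
}

# Independent brute-force two-sided Fisher p (point-probability rule) by
# direct enumeration of all tables with the observed margins.
bf_fisher_p <- function(m) {
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1]); n <- sum(m)
  ks <- max(0L, c1 - r2):min(r1, c1)
  probs <- choose(c1, ks) * choose(n - c1, r1 - ks) / choose(n, r1)
  p_obs <- choose(c1, m[1, 1]) * choose(n - c1, r1 - m[1, 1]) / choose(n, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
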