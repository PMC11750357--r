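test_that("identical seeds regenerate byte-identical datasets", {
  d1 <- file.path(tempdir(), "det-a")
  d2 <- file.path(tempdir(), "det-b")
  run_simulate("event-I-only", d1, seed = 404L)
  run_simulate("event-I-only", d2, seed = 404L)
  files <- sort(list.files(d1, recursive = TRUE))
  expect_identical(files, sort(list.files(d2, recursive = TRUE)))
  for (f in files)
    expect_identical(readBin(file.path(d1, f), "raw", 10e6),
                     readBin(file.path(d2, f), "raw", 10e6))
  # a different seed produces different sequence content
  d3 <- file.path(tempdir(), "det-c")
  run_simulate("event-I-only", d3, seed = 405L)
  fa <- file.path("scaffolds", "Leptopilina_boulardi.fasta")
  expect_false(identical(readBin(file.path(d1, fa), "raw", 10e6),
                         readBin(file.path(d3, fa), "raw", 10e6)))
  unlink(c(d1, d2, d3), recursive = TRUE)
})

test_that("a zero-event scenario emits no viral hits and an empty truth", {
  d <- file.path(tempdir(), "empty-sc")
  ds <- run_simulate("empty", d)
  expect_equal(nrow(ds$truth_loci), 0L)
  hits <- read_hits(file.path(d, "viral_hits.tsv"))
  expect_equal(nrow(hits), 0L)
  unlink(d, recursive = TRUE)
})

test_that("invalid configurations fail naming the offending field", {
  cfg <- study_mimic_scenario()
  bad <- cfg
  bad$events[[1]]$donor_lineage <- "NoSuchFV-like"
  expect_error(validate_scenario_config(bad), "donor_lineage")
  bad2 <- cfg
  bad2$events[[1]]$gene_families <- c(bad2$events[[1]]$gene_families,
                                      "not-a-gene")
  expect_error(validate_scenario_config(bad2), "gene_families")
  bad3 <- cfg
  bad3$events[[1]]$colocation_groups[[1]]$members <-
    rbind(bad3$events[[1]]$colocation_groups[[1]]$members,
          bad3$events[[1]]$colocation_groups[[1]]$members[1, ])
  expect_error(validate_scenario_config(bad3), "two groups")
  expect_error(scenario_preset("nope"), "unknown preset")
})

test_that("simulated gene trees have the planted structural patterns", {
  fx <- mimic_fixture()
  md <- read_tip_metadata(file.path(fx$dir, "tip_metadata.tsv"))
  truth <- fx$ds$truth_loci
  # an event-I-only family: all wasp tips form one clade sister to LhFV
  tr <- ape::read.tree(file.path(fx$dir, "trees", "lef-4.nwk"))
  wasp <- intersect(tr$tip.label, truth$locus_id)
  expect_gt(length(wasp), 2L)
  mrca <- ape::getMRCA(tr, wasp)
  expect_setequal(ape::extract.clade(tr, mrca)$tip.label, wasp)
  parent <- tr$edge[tr$edge[, 2] == mrca, 1]
  sibs <- setdiff(tr$edge[tr$edge[, 1] == parent, 2], mrca)
  sib_tips <- unlist(lapply(sibs, function(n)
    if (n <= ape::Ntip(tr)) tr$tip.label[n] else
      ape::extract.clade(tr, n)$tip.label))
  expect_equal(sib_tips, "LhFV")
  # a shared family: one LhFV-adjacent clade plus an LbFV-adjacent
  # Rhoptromeris attachment
  tr2 <- ape::read.tree(file.path(fx$dir, "trees", "orf11.nwk"))
  wasp2 <- intersect(tr2$tip.label, truth$locus_id)
  rhop <- intersect(wasp2, truth$locus_id[
    truth$species == "Rhoptromeris_sp" & truth$event_id %in% "recent"])
  anc <- setdiff(wasp2, rhop)
  expect_gt(length(rhop), 0L)
  m_anc <- ape::getMRCA(tr2, anc)
  expect_setequal(ape::extract.clade(tr2, m_anc)$tip.label, anc)
  expect_false(any(rhop %in% ape::extract.clade(tr2, m_anc)$tip.label))
})

test_that("a support floor of 100 makes every label parse to 100", {
  cfg <- study_mimic_scenario()
  nwk <- simulate_gene_tree("lef-4", cfg$events, cfg$species_tree,
                            cfg$virus_panel,
                            tree_noise = list(true_ufboot = c(100L, 100L),
                                              spurious_ufboot = c(100L, 100L)),
                            seed = 1L)
  tr <- ape::read.tree(text = nwk)
  sup <- parse_support(tr$node.label[nzchar(tr$node.label)])
  expect_true(all(sup == 100))
})

test_that("a family absent from every repertoire is an error", {
  cfg <- study_mimic_scenario()
  expect_error(simulate_gene_tree("no-such-family", cfg$events,
                                  cfg$species_tree, cfg$virus_panel),
               "absent from every virus repertoire")
})

test_that("codon simulation respects branch lengths and pseudogenization", {
  tree <- ape::read.tree(text = "((a:0,b:0):0,(c:0,d:0):0);")
  aln <- simulate_codon_alignment(tree, omega = 0.5, n_codons = 60, seed = 2)
  expect_true(all(aln == aln[1]))            # zero branch lengths
  expect_equal(unique(nchar(aln)), 180L)     # 3 x n_codons
  stops <- c("TAA", "TAG", "TGA")
  has_stop <- function(s) any(waspEVE:::split_codons(s) %in% stops)
  tree2 <- ape::read.tree(text = "((a:0.1,b:0.1):0.1,(c:0.1,d:0.1):0.1);")
  aln2 <- simulate_codon_alignment(tree2, omega = 0.5, n_codons = 60, seed = 3)
  expect_false(any(vapply(aln2, has_stop, logical(1))))
  expect_true(has_stop(pseudogenize(aln2[[1]])))
  expect_error(simulate_codon_alignment(tree2, omega = 0, n_codons = 60),
               "omega")
})

test_that("every truth locus is recoverable from the emitted hit table", {
  fx <- mimic_fixture()
  hits <- filter_hits(read_hits(file.path(fx$dir, "viral_hits.tsv")))
  truth <- fx$ds$truth_loci
  for (i in seq_len(nrow(truth))) {
    match_i <- hits$qseqid == truth$scaffold[i] &
      hits$start == truth$start[i] & hits$end == truth$end[i] &
      hits$strand == truth$strand[i]
    expect_true(any(match_i), info = truth$locus_id[i])
  }
  # each truth locus appears exactly once in the catalog
  expect_equal(anyDuplicated(truth$locus_id), 0L)
})

test_that("the mimic truth table carries the study-scale counts", {
  fx <- mimic_fixture()
  truth <- fx$ds$truth_loci
  expect_equal(nrow(truth), 153L)
  expect_length(unique(truth$species), 6L)
  ev <- fx$ds$truth_events
  expect_equal(sort(ev$n_families), c(9L, 18L))
  fams1 <- strsplit(ev$families[ev$event_id == "ancestral"], ",")[[1]]
  fams2 <- strsplit(ev$families[ev$event_id == "recent"], ",")[[1]]
  expect_length(intersect(fams1, fams2), 5L)
  expect_equal(sum(is.na(truth$event_id)), 3L)
  expect_equal(as.integer(table(fx$ds$truth_families$true_type)[
    c("TYPE_I", "TYPE_II", "TYPE_III", "UNCLASSIFIED")]),
    c(12L, 3L, 5L, 5L))
})
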