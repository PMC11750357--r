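## Scenario configuration for the synthetic-data generator: a species
## chronogram, a virus panel with gene repertoires, endogenization-event
## specifications, genome/coverage parameters, tree-noise settings and
## per-family codon-evolution parameters.

#' Specify one endogenization event
#'
#' @param event_id Identifier (e.g. `"event_1"`).
#' @param donor_lineage Viral lineage tag of the donor (must match a panel
#'   virus).
#' @param recipient_species Species descending from the branch where the
#'   insertion occurred (all of them receive the event's families unless
#'   lost).
#' @param gene_families Families acquired in the event.
#' @param losses Named list, species -> character vector of families lost
#'   in that species.
#' @param paralog_counts Data frame `species`, `family`, `n` (copy numbers
#'   greater than one).
#' @param pseudogenized Data frame `species`, `family`, `copy`, `status`
#'   (`premature_stop` or `incomplete`) for degraded copies.
#' @param colocation_groups List of groups, each
#'   `list(species =, members = data.frame(family, copy))`: copies placed
#'   together on one scaffold. A copy may appear in at most one group.
#' @param unclassifiable_families Families of this event whose gene trees
#'   are emitted with low (spurious-range) support so the topology
#'   classifier cannot resolve them.
#' @return An `event_spec` list.
#' @export
event_spec <- function(event_id, donor_lineage, recipient_species,
                       gene_families, losses = list(),
                       paralog_counts = data.frame(
                         species = character(0), family = character(0),
                         n = integer(0)),
                       pseudogenized = data.frame(
                         species = character(0), family = character(0),
                         copy = integer(0), status = character(0)),
                       colocation_groups = list(),
                       unclassifiable_families = character(0)) {
  ev <- list(event_id = event_id, donor_lineage = donor_lineage,
             recipient_species = recipient_species,
             gene_families = gene_families, losses = losses,
             paralog_counts = paralog_counts, pseudogenized = pseudogenized,
             colocation_groups = colocation_groups,
             unclassifiable_families = unclassifiable_families)
  class(ev) <- "event_spec"
  ev
}

#' Assemble a scenario configuration
#'
#' @param seed Integer seed; fully determines all generated output.
#' @param species_tree Chronogram newick (node ages in Myr as labels, see
#'   [read_chronogram()]).
#' @param virus_panel List of viruses, each
#'   `list(name, lineage, repertoire = data.frame(family, core))`.
#' @param events List of [event_spec()] objects.
#' @param orphans List of `list(species, family, donor_virus)`: loci not
#'   linkable to any event (isolated scaffold, unclassifiable tree).
#' @param genome_params List: `gc_mean`, `gc_sd`, `insert_gc_offset`
#'   (0 keeps viral inserts at host composition), `cov_mean`, `cov_sd`,
#'   `n_busco_scaffolds`, `n_host_scaffolds` (per species).
#' @param tree_noise List of support ranges: `true_ufboot`,
#'   `spurious_ufboot`, `true_alrt`, `spurious_alrt`. True-clade ranges
#'   must sit strictly above the classification threshold and spurious
#'   ranges strictly below it.
#' @param omega_params List: `omega` (named per-family dN/dS; `default`
#'   entry used otherwise), `kappa`, `n_codons`.
#' @param start_codons List: `default` plus `by_family` overrides
#'   (`list(family = list(default =, overrides = c(species = codon)))`).
#' @return A validated `scenario_config`.
#' @export
scenario_config <- function(seed, species_tree, virus_panel, events,
                            orphans = list(),
                            genome_params = list(),
                            tree_noise = list(),
                            omega_params = list(),
                            start_codons = list(default = "ATG",
                                                by_family = list())) {
  gp <- utils::modifyList(list(
    gc_mean = 0.35, gc_sd = 0.02, insert_gc_offset = 0,
    cov_mean = 60, cov_sd = 8,
    n_busco_scaffolds = 12L, n_host_scaffolds = 4L), genome_params)
  tn <- utils::modifyList(list(
    true_ufboot = c(91L, 100L), spurious_ufboot = c(40L, 79L),
    true_alrt = c(85, 100), spurious_alrt = c(20, 80)), tree_noise)
  op <- utils::modifyList(list(
    omega = c(default = 0.15), kappa = 1.5, n_codons = 200L), omega_params)
  cfg <- list(seed = as.integer(seed), species_tree = species_tree,
              virus_panel = virus_panel, events = events, orphans = orphans,
              genome_params = gp, tree_noise = tn, omega_params = op,
              start_codons = start_codons)
  class(cfg) <- "scenario_config"
  validate_scenario_config(cfg)
  cfg
}

#' Validate a scenario configuration
#'
#' Checks the species-tree age invariants, that every event's donor lineage
#' exists in the panel, that every event family is in the donor's
#' repertoire, that losses/pseudogenization/paralog tables reference
#' recipient species, and that colocation groups form a partition (no copy
#' in two groups). Errors name the offending field.
#' @param config A `scenario_config`.
#' @return The config, invisibly.
#' @export
validate_scenario_config <- function(config) {
  chrono <- tryCatch(read_chronogram(config$species_tree),
                     error = function(e)
                       stop("species_tree: ", conditionMessage(e)))
  tips <- chrono$tree$tip.label
  lineages <- vapply(config$virus_panel, `[[`, character(1), "lineage")
  vnames <- vapply(config$virus_panel, `[[`, character(1), "name")
  for (ev in config$events) {
    if (!ev$donor_lineage %in% lineages)
      stop("events/", ev$event_id, "/donor_lineage: unknown lineage '",
           ev$donor_lineage, "'")
    donor <- config$virus_panel[[match(ev$donor_lineage, lineages)]]
    missing_fam <- setdiff(ev$gene_families, donor$repertoire$family)
    if (length(missing_fam))
      stop("events/", ev$event_id, "/gene_families: not in donor (",
           donor$name, ") repertoire: ", paste(missing_fam, collapse = ", "))
    bad_sp <- setdiff(ev$recipient_species, tips)
    if (length(bad_sp))
      stop("events/", ev$event_id, "/recipient_species: not in species tree: ",
           paste(bad_sp, collapse = ", "))
    for (sp in names(ev$losses))
      if (!sp %in% ev$recipient_species)
        stop("events/", ev$event_id, "/losses: species '", sp,
             "' is not a recipient")
    seen <- character(0)
    for (g in ev$colocation_groups) {
      keys <- paste(g$species, g$members$family, g$members$copy)
      dup <- c(keys[duplicated(keys)], intersect(keys, seen))
      if (length(dup))
        stop("events/", ev$event_id,
             "/colocation_groups: copy in two groups: ", dup[1])
      seen <- c(seen, keys)
    }
  }
  for (o in config$orphans)
    if (!o$donor_virus %in% vnames)
      stop("orphans/donor_virus: unknown virus '", o$donor_virus, "'")
  if (config$omega_params$n_codons < 50L)
    stop("omega_params/n_codons must be >= 50")
  invisible(config)
}

.EVENT1_FAMILIES <- c("lef-4", "lef-8", "lef-9", "p74", "pif-1", "pif-2",
                      "pif-3", "ac81", "lcat", "orf96", "orf83", "lef-5",
                      "orf44",
                      "orf10", "orf11", "orf58", "orf78", "orf92")
.SHARED_FAMILIES <- c("orf10", "orf11", "orf58", "orf78", "orf92")
.EVENT2_FAMILIES <- c(.SHARED_FAMILIES, "orf85", "orf94", "odv-e66", "orf105")
.ORPHAN_FAMILIES <- c("orf30", "orf47", "orf60")
.CORE_FAMILIES <- c("lef-4", "lef-8", "lef-9", "p74", "pif-1", "pif-2",
                    "pif-3", "ac81", "lef-5", "orf10", "orf11", "orf58")
.POSITIVE_SPECIES <- c("Leptopilina_heterotoma", "Leptopilina_clavipes",
                       "Leptopilina_boulardi", "Trichoplasta_sp",
                       "Rhoptromeris_sp", "Trybliographa_sp")

.mimic_virus_panel <- function() {
  all_fams <- unique(c(.EVENT1_FAMILIES, .EVENT2_FAMILIES))
  rep_for <- function(fams, n_total, n_core, prefix) {
    fill <- sprintf("%sg%03d", prefix, seq_len(n_total - length(fams)))
    core <- c(fams %in% .CORE_FAMILIES,
              seq_along(fill) <= (n_core - sum(fams %in% .CORE_FAMILIES)))
    data.frame(family = c(fams, fill), core = core,
               stringsAsFactors = FALSE)
  }
  list(
    list(name = "LhFV", lineage = "LhFV-like",
         repertoire = rep_for(all_fams, 110L, 29L, "LhFV")),
    list(name = "LbFV", lineage = "LbFV-like",
         repertoire = rep_for(all_fams, 98L, 26L, "LbFV")),
    list(name = "DfFV", lineage = "other-FV",
         repertoire = rep_for(c(all_fams, .ORPHAN_FAMILIES), 90L, 24L, "DfFV")),
    list(name = "CcFV", lineage = "other-FV",
         repertoire = rep_for(all_fams, 85L, 24L, "CcFV")),
    list(name = "EfFV", lineage = "other-FV",
         repertoire = rep_for(c(all_fams, .ORPHAN_FAMILIES), 88L, 23L, "EfFV")),
    list(name = "GpSGHV", lineage = "outgroup",
         repertoire = rep_for(c(all_fams, .ORPHAN_FAMILIES), 100L, 28L, "GpSGHV")),
    list(name = "MdSGHV", lineage = "outgroup",
         repertoire = rep_for(c(all_fams, .ORPHAN_FAMILIES), 108L, 28L, "MdSGHV")))
}

#' The fixed study-mimic scenario
#'
#' A two-event endogenization scenario over six EVE-positive cynipoid
#' species (three *Leptopilina*, *Trichoplasta*, *Rhoptromeris*,
#' *Trybliographa*) plus three negative relatives: an ancestral event of 18
#' gene families from an LhFV-like donor at the common ancestor of the six,
#' and a recent event of 9 families (5 shared with the first) from an
#' LbFV-like donor on the *Rhoptromeris* branch yielding 16 copies, 7 of
#' them with premature stops or incomplete ORFs; plus 3 orphan loci not
#' linkable to either event. Colocation groups are arranged so that the
#' transitive-closure grouping recovers exactly the two events (150 of 153
#' loci assigned). One family per event emits a low-support
#' (unclassifiable) tree, as do the three orphans, so topology
#' classification yields 12 type I, 3 type II, 5 type III and 5
#' unclassified families.
#'
#' @param seed Integer seed (default 19530). The scenario's structural
#'   counts are planted by construction and do not depend on the seed;
#'   sequences, branch lengths and support draws do.
#' @return A `scenario_config`.
#' @export
study_mimic_scenario <- function(seed = 19530L) {
  lhet <- "Leptopilina_heterotoma"
  lcla <- "Leptopilina_clavipes"
  lbou <- "Leptopilina_boulardi"
  tric <- "Trichoplasta_sp"
  rhop <- "Rhoptromeris_sp"
  tryb <- "Trybliographa_sp"
  a_fams <- .EVENT1_FAMILIES[1:12]
  u1 <- "orf44"
  pc1 <- rbind(
    data.frame(species = lbou, family = a_fams[1:8], n = 3L),
    data.frame(species = lbou, family = a_fams[9:10], n = 2L),
    data.frame(species = lhet, family = a_fams[1:6], n = 2L),
    data.frame(species = lhet, family = u1, n = 2L),
    data.frame(species = lbou, family = u1, n = 2L),
    data.frame(species = lcla, family = a_fams[1:3], n = 2L),
    data.frame(species = tryb, family = .SHARED_FAMILIES[1:3], n = 2L),
    data.frame(species = tric, family = a_fams[4:5], n = 2L),
    data.frame(species = rhop, family = a_fams[1], n = 2L))
  grp <- function(sp, fams, copies) {
    list(species = sp,
         members = data.frame(family = fams, copy = copies,
                              stringsAsFactors = FALSE))
  }
  ev1 <- event_spec(
    event_id = "ancestral", donor_lineage = "LhFV-like",
    recipient_species = .POSITIVE_SPECIES,
    gene_families = .EVENT1_FAMILIES,
    losses = stats::setNames(
      list(u1, u1, c(u1, .SHARED_FAMILIES), u1),
      c(lcla, tric, rhop, tryb)),
    paralog_counts = pc1,
    pseudogenized = data.frame(
      species = c(lbou, lcla), family = c(a_fams[9], a_fams[3]),
      copy = c(2L, 1L), status = c("premature_stop", "premature_stop"),
      stringsAsFactors = FALSE),
    colocation_groups = list(
      grp(lbou, c(a_fams[1:6], u1), c(rep(1L, 6), 1L)),
      grp(lbou, c(a_fams[7:12], u1), c(rep(1L, 6), 2L)),
      grp(lhet, c(a_fams[6:7], u1), c(1L, 1L, 2L)),
      grp(lhet, c(.SHARED_FAMILIES, a_fams[1], u1),
          c(rep(1L, 5), 1L, 1L))),
    unclassifiable_families = u1)
  u2 <- "orf105"
  pc2 <- data.frame(
    species = rhop,
    family = c("orf10", "orf85", "orf94", "odv-e66", u2),
    n = c(2L, 2L, 2L, 4L, 2L), stringsAsFactors = FALSE)
  ev2 <- event_spec(
    event_id = "recent", donor_lineage = "LbFV-like",
    recipient_species = rhop,
    gene_families = .EVENT2_FAMILIES,
    paralog_counts = pc2,
    pseudogenized = data.frame(
      species = rhop,
      family = c("orf11", "orf85", u2, "odv-e66", "odv-e66", "orf58", u2),
      copy = c(1L, 2L, 1L, 2L, 3L, 1L, 2L),
      status = c("premature_stop", "premature_stop", "premature_stop",
                 "premature_stop", "premature_stop", "incomplete",
                 "incomplete"),
      stringsAsFactors = FALSE),
    colocation_groups = list(
      grp(rhop, c("orf10", "orf11", "orf85", u2, "odv-e66"),
          c(1L, 1L, 1L, 1L, 1L)),
      grp(rhop, c("orf58", "orf78", "orf85", "orf94", u2),
          c(1L, 1L, 2L, 1L, 2L)),
      grp(rhop, c("orf92", "orf10", "orf94", "odv-e66", "odv-e66", "odv-e66"),
          c(1L, 2L, 2L, 2L, 3L, 4L))),
    unclassifiable_families = u2)
  orphans <- list(
    list(species = lbou, family = "orf30", donor_virus = "EfFV"),
    list(species = tryb, family = "orf47", donor_virus = "EfFV"),
    list(species = tric, family = "orf60", donor_virus = "DfFV"))
  omega <- c(default = 0.15, "odv-e66" = 1.0, "lef-5" = 0.11,
             "orf10" = 0.165, "orf85" = 0.3, "orf94" = 0.3,
             "orf105" = 0.3, "orf30" = 0.5, "orf47" = 0.5, "orf60" = 0.5)
  scenario_config(
    seed = seed,
    species_tree = cynipoid_chronogram_newick(),
    virus_panel = .mimic_virus_panel(),
    events = list(ev1, ev2), orphans = orphans,
    omega_params = list(omega = omega, kappa = 1.5, n_codons = 200L),
    start_codons = list(
      default = "ATG",
      by_family = list(
        "lef-5" = list(default = "TTG",
                       overrides = c(Leptopilina_heterotoma = "ATG",
                                     Trichoplasta_sp = "ATG",
                                     Leptopilina_clavipes = "CTG")))))
}

#' Named scenario presets
#'
#' `"study-mimic"`: the full two-event scenario ([study_mimic_scenario()]);
#' `"event-I-only"`: the ancestral event alone (no recent event, no
#' orphans); `"empty"`: no events, no orphans (negative control).
#'
#' @param name Preset name.
#' @param seed Integer seed.
#' @return A `scenario_config`.
#' @export
scenario_preset <- function(name, seed = 19530L) {
  known <- c("study-mimic", "event-I-only", "empty")
  if (!name %in% known)
    stop("unknown preset '", name, "'; available: ",
         paste(known, collapse = ", "))
  cfg <- study_mimic_scenario(seed)
  if (name == "event-I-only") {
    cfg$events <- cfg$events[1]
    cfg$orphans <- list()
  } else if (name == "empty") {
    cfg$events <- list()
    cfg$orphans <- list()
  }
  validate_scenario_config(cfg)
  cfg
}
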