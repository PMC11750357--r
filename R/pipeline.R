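## Stage orchestration. Every stage consumes files (a dataset directory
## written by the generator plus the previous stages' outputs under a
## results directory), never in-memory state, so each is individually
## re-runnable; run_all() chains them and writes a combined JSON report.

.read_manifest <- function(data_dir) {
  mf <- file.path(data_dir, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json in ", data_dir)
  jsonlite::read_json(mf, simplifyVector = TRUE)
}

.read_truth_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, quote = "")
}

#' Generate a synthetic dataset from a preset or config
#'
#' @param scenario A [scenario_config()] or a preset name (see
#'   [scenario_preset()]).
#' @param out_dir Output directory (created if missing).
#' @param seed Seed used when `scenario` is a preset name.
#' @return The `synthetic_dataset` (invisibly the manifest records the
#'   seed).
#' @export
run_simulate <- function(scenario, out_dir, seed = 19530L) {
  cfg <- if (inherits(scenario, "scenario_config")) scenario else
    scenario_preset(scenario, seed = seed)
  generate_scenario(cfg, out_dir)
}

#' Detection stage: EVE catalog and integration evidence
#'
#' Filters viral homology hits at the e-value ceiling, calls loci by
#' same-strand interval union, annotates ORF integrity from the scaffold
#' sequences, and scores every EVE-candidate scaffold against its
#' species' BUSCO GC/coverage envelope plus gene/TE evidence.
#'
#' @param data_dir Dataset directory (with `manifest.json`).
#' @param out_dir Results directory (default `<data_dir>/results`).
#' @param e_max Inclusive e-value ceiling (default 1e-3).
#' @param envelope_k Envelope half-width in MADs (default 5).
#' @return List with `catalog` and `evidence` data frames (also written as
#'   TSV).
#' @export
run_detect <- function(data_dir, out_dir = file.path(data_dir, "results"),
                       e_max = 1e-3, envelope_k = 5) {
  manifest <- .read_manifest(data_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  scaffolds <- .read_truth_tsv(file.path(data_dir,
                                         manifest$files$scaffold_table))
  coverage <- .read_truth_tsv(file.path(data_dir, manifest$files$coverage))
  busco_ids <- readLines(file.path(data_dir,
                                   manifest$files$busco_scaffolds))
  seqs <- character(0)
  for (fp in manifest$files$scaffolds)
    seqs <- c(seqs, as.character(Biostrings::readDNAStringSet(
      file.path(data_dir, fp))))
  gc <- vapply(seqs, gc_content, numeric(1))
  sc_meta <- data.frame(
    scaffold = names(seqs),
    gc = unname(gc[names(seqs)]),
    coverage = coverage$mean_coverage[match(names(seqs),
                                            coverage$scaffold)],
    species = scaffolds$species[match(names(seqs), scaffolds$scaffold)],
    stringsAsFactors = FALSE)
  hits <- read_hits(file.path(data_dir, manifest$files$viral_hits))
  hits <- filter_hits(hits, e_max)
  sp_map <- stats::setNames(sc_meta$species, sc_meta$scaffold)
  catalog <- call_loci(hits, species = sp_map)
  catalog <- annotate_orf_integrity(catalog, seqs)
  taxonomy <- .read_truth_tsv(file.path(data_dir, manifest$files$taxonomy))
  te_hits <- read_hits(file.path(data_dir, manifest$files$te_hits))
  evidence <- list()
  for (scf in unique(catalog$scaffold)) {
    rec <- sc_meta[sc_meta$scaffold == scf, ]
    busco_sp <- sc_meta[sc_meta$scaffold %in% busco_ids &
                        sc_meta$species == rec$species, ]
    env <- busco_envelope(busco_sp, k = envelope_k)
    evidence[[length(evidence) + 1L]] <- classify_scaffold(
      rec, env,
      gene_labels = taxonomy$taxon[taxonomy$scaffold == scf],
      te_hits = te_hits[te_hits$qseqid == scf, , drop = FALSE])
  }
  evidence <- if (length(evidence)) do.call(rbind, evidence) else
    data.frame(scaffold = character(0), verdict = character(0))
  .write_tsv(catalog, file.path(out_dir, "eve_catalog.tsv"))
  .write_tsv(evidence, file.path(out_dir, "scaffold_evidence.tsv"))
  list(catalog = catalog, evidence = evidence)
}

#' Classification stage: per-family topology calls
#'
#' @inheritParams run_detect
#' @param min_support Strict ultrafast-bootstrap threshold (default 80).
#' @return Named list of `topology_call`s (also written as TSV and JSON).
#' @export
run_classify <- function(data_dir, out_dir = file.path(data_dir, "results"),
                         min_support = 80) {
  manifest <- .read_manifest(data_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  metadata <- read_tip_metadata(file.path(data_dir,
                                          manifest$files$tip_metadata))
  calls <- list()
  for (tp in manifest$files$trees) {
    fam <- sub("\\.nwk$", "", basename(tp))
    tree <- ape::read.tree(file.path(data_dir, tp))
    calls[[fam]] <- classify_gene_tree(tree, metadata,
                                       min_support = min_support,
                                       family = fam)
  }
  if (length(calls)) {
    .write_tsv(topology_call_table(calls),
               file.path(out_dir, "topology_calls.tsv"))
    jsonlite::write_json(
      lapply(calls, function(x) {
        list(family = x$family, type = x$type, notes = x$notes,
             clades = lapply(x$clades, function(cl)
               list(tips = cl$tips, species = cl$species,
                    support = cl$support,
                    nearest_lineage = cl$nearest_lineage)))
      }),
      file.path(out_dir, "topology_calls.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null")
  } else {
    jsonlite::write_json(stats::setNames(list(), character(0)),
                         file.path(out_dir, "topology_calls.json"))
  }
  calls
}

.read_calls_json <- function(path) {
  raw <- jsonlite::read_json(path)
  lapply(raw, function(x) {
    structure(list(
      family = x$family, type = x$type,
      notes = unlist(x$notes),
      clades = lapply(x$clades, function(cl)
        list(tips = unlist(cl$tips), species = unlist(cl$species),
             support = if (is.null(cl$support)) NA_real_ else cl$support,
             nearest_lineage = cl$nearest_lineage))),
      class = "topology_call")
  })
}

#' Assignment stage: loci to endogenization events
#'
#' @inheritParams run_detect
#' @return List with `events` and `unassigned` (also written as JSON and a
#'   TSV summary).
#' @export
run_assign <- function(data_dir, out_dir = file.path(data_dir, "results")) {
  cat_path <- file.path(out_dir, "eve_catalog.tsv")
  calls_path <- file.path(out_dir, "topology_calls.json")
  if (!file.exists(cat_path)) stop("missing detect-stage output: ", cat_path)
  if (!file.exists(calls_path))
    stop("missing classify-stage output: ", calls_path)
  catalog <- .read_truth_tsv(cat_path)
  calls <- .read_calls_json(calls_path)
  grouped <- if (nrow(catalog)) {
    graph <- build_graph(catalog, calls)
    group_events(graph, calls)
  } else list(events = list(), unassigned = character(0))
  jsonlite::write_json(grouped, file.path(out_dir, "events.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  ev_tab <- do.call(rbind, lapply(grouped$events, function(ev)
    data.frame(event_id = ev$event_id, n_loci = ev$n_loci,
               n_families = length(ev$families),
               n_species = length(ev$species),
               donor_lineage = ev$donor_lineage,
               conflict = ev$conflict,
               species = paste(ev$species, collapse = ","),
               families = paste(ev$families, collapse = ","),
               stringsAsFactors = FALSE)))
  if (is.null(ev_tab))
    ev_tab <- data.frame(event_id = character(0), n_loci = integer(0))
  .write_tsv(ev_tab, file.path(out_dir, "events.tsv"))
  grouped
}

#' Selection stage: per-family dN/dS and EVE-vs-BUSCO comparison
#'
#' Families with fewer than 2 sequences are reported `undetermined`
#' (dN/dS not computable). The group comparison pools pairwise omegas of
#' all EVE families against those of the BUSCO reference genes.
#'
#' @inheritParams run_detect
#' @param alpha Significance level for the regime call.
#' @return List with `omega_table` (data frame) and `comparison`.
#' @export
run_select <- function(data_dir, out_dir = file.path(data_dir, "results"),
                       alpha = 0.05) {
  manifest <- .read_manifest(data_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  eve_pair_omegas <- numeric(0)
  for (ap in manifest$files$alignments) {
    fam <- sub("\\.fasta$", "", basename(ap))
    seqs <- as.character(Biostrings::readDNAStringSet(file.path(data_dir, ap)))
    if (length(seqs) < 2L) {
      rows[[length(rows) + 1L]] <- data.frame(
        family = fam, n_seqs = length(seqs), mean_omega = NA_real_,
        se_omega = NA_real_, n_pairs = 0L, n_undefined = 0L,
        regime = "undetermined", stringsAsFactors = FALSE)
      next
    }
    est <- family_omega(seqs, family = fam, alpha = alpha)
    eve_pair_omegas <- c(eve_pair_omegas,
                         est$pairs$omega[is.finite(est$pairs$omega)])
    rows[[length(rows) + 1L]] <- data.frame(
      family = fam, n_seqs = length(seqs), mean_omega = est$mean_omega,
      se_omega = est$se_omega, n_pairs = est$n_pairs,
      n_undefined = est$n_undefined, regime = est$regime,
      stringsAsFactors = FALSE)
  }
  omega_table <- if (length(rows)) do.call(rbind, rows) else
    data.frame(family = character(0))
  busco_pair_omegas <- numeric(0)
  for (bp in manifest$files$busco_alignments) {
    seqs <- as.character(Biostrings::readDNAStringSet(file.path(data_dir, bp)))
    if (length(seqs) < 2L) next
    est <- family_omega(seqs, family = basename(bp), alpha = alpha)
    busco_pair_omegas <- c(busco_pair_omegas,
                           est$pairs$omega[is.finite(est$pairs$omega)])
  }
  comparison <- if (length(eve_pair_omegas) >= 2L &&
                    length(busco_pair_omegas) >= 2L) {
    compare_groups(eve_pair_omegas, busco_pair_omegas)
  } else NULL
  .write_tsv(omega_table, file.path(out_dir, "omega_table.tsv"))
  jsonlite::write_json(list(comparison = comparison),
                       file.path(out_dir, "selection_comparison.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  list(omega_table = omega_table, comparison = comparison)
}

#' Dating stage: map events onto the chronogram
#'
#' @inheritParams run_detect
#' @return List of per-event age intervals (also written as JSON).
#' @export
run_date <- function(data_dir, out_dir = file.path(data_dir, "results")) {
  manifest <- .read_manifest(data_dir)
  ev_path <- file.path(out_dir, "events.json")
  if (!file.exists(ev_path)) stop("missing assign-stage output: ", ev_path)
  grouped <- jsonlite::read_json(ev_path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE)
  chrono <- read_chronogram(file.path(data_dir, manifest$files$chronogram))
  dated <- lapply(grouped$events, function(ev) {
    sp <- unlist(ev$species)
    d <- date_event(sp, chrono)
    list(event_id = ev$event_id, species = sp,
         lower_age = d$lower_age, lower_ci = d$lower_ci,
         upper_age = d$upper_age, upper_ci = d$upper_ci)
  })
  jsonlite::write_json(dated, file.path(out_dir, "event_dating.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  dated
}

#' Reporting stage: species-by-family presence matrix
#'
#' @inheritParams run_detect
#' @return The presence matrix (character; also written as TSV).
#' @export
run_report <- function(data_dir, out_dir = file.path(data_dir, "results")) {
  cat_path <- file.path(out_dir, "eve_catalog.tsv")
  if (!file.exists(cat_path)) stop("missing detect-stage output: ", cat_path)
  catalog <- .read_truth_tsv(cat_path)
  m <- if (nrow(catalog)) presence_matrix(catalog) else
    matrix(character(0), 0, 0)
  df <- data.frame(species = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  .write_tsv(df, file.path(out_dir, "presence_matrix.tsv"))
  m
}

#' Run the full pipeline on a dataset directory
#'
#' detect -> classify -> assign -> select -> date -> enrichment -> report;
#' writes per-stage TSV/JSON outputs plus a combined `report.json`.
#'
#' @inheritParams run_detect
#' @inheritParams run_classify
#' @param alpha Significance level for the selection-regime call.
#' @return List with `catalog`, `evidence`, `calls`, `events`,
#'   `unassigned`, `omega_table`, `comparison`, `enrichment`, `dating`,
#'   `presence`.
#' @export
run_all <- function(data_dir, out_dir = file.path(data_dir, "results"),
                    e_max = 1e-3, min_support = 80, envelope_k = 5,
                    alpha = 0.05) {
  det <- run_detect(data_dir, out_dir, e_max = e_max,
                    envelope_k = envelope_k)
  calls <- run_classify(data_dir, out_dir, min_support = min_support)
  grouped <- run_assign(data_dir, out_dir)
  sel <- run_select(data_dir, out_dir, alpha = alpha)
  dated <- run_date(data_dir, out_dir)
  ## core-gene enrichment per event against its donor's repertoire
  manifest <- .read_manifest(data_dir)
  panel <- .read_truth_tsv(file.path(data_dir, manifest$files$virus_panel))
  enrichment <- lapply(grouped$events, function(ev) {
    donor_viruses <- unique(panel$virus[panel$lineage == ev$donor_lineage])
    if (!length(donor_viruses) || is.na(ev$donor_lineage)) return(NULL)
    rep_df <- panel[panel$virus == donor_viruses[1],
                    c("family", "core"), drop = FALSE]
    res <- core_gene_enrichment(ev$families, rep_df)
    list(event_id = ev$event_id, donor_virus = donor_viruses[1],
         n_event = res$n_event, n_event_core = res$n_event_core,
         n_donor = res$n_donor, n_donor_core = res$n_donor_core,
         odds_ratio = res$odds_ratio, p = res$p)
  })
  enrichment <- Filter(Negate(is.null), enrichment)
  presence <- run_report(data_dir, out_dir)
  report <- list(
    n_loci = nrow(det$catalog),
    n_events = length(grouped$events),
    n_unassigned = length(grouped$unassigned),
    events = lapply(grouped$events, function(ev)
      ev[c("event_id", "n_loci", "families", "species", "donor_lineage",
           "conflict")]),
    unassigned = grouped$unassigned,
    topology_type_counts = as.list(table(
      vapply(calls, `[[`, character(1), "type"))),
    enrichment = enrichment,
    dating = dated,
    selection_comparison = sel$comparison)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  list(catalog = det$catalog, evidence = det$evidence, calls = calls,
       events = grouped$events, unassigned = grouped$unassigned,
       omega_table = sel$omega_table, comparison = sel$comparison,
       enrichment = enrichment, dating = dated, presence = presence,
       report = report)
}
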