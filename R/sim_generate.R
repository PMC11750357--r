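## Scenario generation: plans every EVE copy implied by the event specs,
## assigns scaffolds and coordinates, simulates gene trees and codon
## alignments, splices planted ORFs into host-composition scaffolds, and
## emits every input file the pipeline consumes together with a
## machine-readable truth table and a JSON manifest.

.start_codon_for <- function(family, species, start_codons) {
  bf <- start_codons$by_family[[family]]
  if (!is.null(bf)) {
    ov <- bf$overrides
    if (!is.null(ov) && species %in% names(ov)) return(unname(ov[species]))
    return(bf$default %||% start_codons$default)
  }
  start_codons$default %||% "ATG"
}

.omega_for <- function(family, omega) {
  if (family %in% names(omega)) return(unname(omega[family]))
  unname(omega["default"])
}

## One row per planted EVE copy.
.plan_loci <- function(config) {
  rows <- list()
  lineages <- vapply(config$virus_panel, `[[`, character(1), "lineage")
  vnames <- vapply(config$virus_panel, `[[`, character(1), "name")
  for (ev in config$events) {
    donor <- vnames[match(ev$donor_lineage, lineages)]
    for (fam in ev$gene_families) {
      copies <- .copies_for(ev, fam)
      for (sp in names(copies)) {
        for (cp in copies[[sp]]) {
          status <- "complete"
          ps <- ev$pseudogenized
          if (nrow(ps)) {
            hit <- ps$status[ps$species == sp & ps$family == fam &
                             ps$copy == cp]
            if (length(hit)) status <- hit[1]
          }
          rows[[length(rows) + 1L]] <- data.frame(
            event_id = ev$event_id, species = sp, family = fam,
            copy = cp, orf_plan = status, donor_virus = donor,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  for (o in config$orphans)
    rows[[length(rows) + 1L]] <- data.frame(
      event_id = NA_character_, species = o$species, family = o$family,
      copy = 1L, orf_plan = "complete", donor_virus = o$donor_virus,
      stringsAsFactors = FALSE)
  if (length(rows) == 0L)
    return(data.frame(event_id = character(0), species = character(0),
                      family = character(0), copy = integer(0),
                      orf_plan = character(0), donor_virus = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

.plan_key <- function(event_id, species, family, copy) {
  paste(ifelse(is.na(event_id), "orphan", event_id),
        species, family, copy, sep = "\r")
}

#' Generate a complete synthetic dataset for a scenario
#'
#' Writes scaffold FASTAs, a coverage TSV, viral and TE hit tables,
#' predicted-protein taxonomy, per-family gene trees with "aLRT/UFboot"
#' labels, tip metadata, in-frame codon alignments (EVE families and a set
#' of BUSCO reference genes), the chronogram, truth tables and a JSON
#' manifest under `out_dir`. The seed in the config fully determines the
#' output (byte-identical regeneration).
#'
#' @param config A [scenario_config()].
#' @param out_dir Output directory (created if missing).
#' @return A `synthetic_dataset`: list with `dir`, `manifest`,
#'   `truth_loci`, `truth_families`, `truth_events`, `config`.
#' @export
generate_scenario <- function(config, out_dir) {
  validate_scenario_config(config)
  set.seed(config$seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (d in c("scaffolds", "trees", "alignments", "alignments_busco", "truth"))
    dir.create(file.path(out_dir, d), showWarnings = FALSE)
  gp <- config$genome_params
  op <- config$omega_params
  chrono <- read_chronogram(config$species_tree)
  all_species <- chrono$tree$tip.label
  plan <- .plan_loci(config)
  positive <- sort(unique(plan$species))
  n_cod <- op$n_codons

  ## ---- scaffold assignment -------------------------------------------
  counters <- stats::setNames(rep(0L, length(all_species)), all_species)
  next_scf <- function(sp) {
    counters[sp] <<- counters[sp] + 1L
    sprintf("%s_scf%03d", sp, counters[sp])
  }
  plan$scaffold <- rep(NA_character_, nrow(plan))
  plan$slot <- rep(NA_integer_, nrow(plan))
  for (ev in config$events) {
    for (g in ev$colocation_groups) {
      scf <- next_scf(g$species)
      for (j in seq_len(nrow(g$members))) {
        i <- which(plan$event_id == ev$event_id &
                   plan$species == g$species &
                   plan$family == g$members$family[j] &
                   plan$copy == g$members$copy[j])
        if (length(i) != 1L)
          stop("colocation_groups: no planned copy for ",
               g$species, "/", g$members$family[j], "/", g$members$copy[j])
        plan$scaffold[i] <- scf
        plan$slot[i] <- j
      }
    }
  }
  for (i in which(is.na(plan$scaffold))) {
    plan$scaffold[i] <- next_scf(plan$species[i])
    plan$slot[i] <- 1L
  }
  scaffold_rows <- list()
  add_scaffold <- function(scf, sp, type, len) {
    scaffold_rows[[length(scaffold_rows) + 1L]] <<- data.frame(
      scaffold = scf, species = sp, type = type, length = len,
      stringsAsFactors = FALSE)
  }

  ## ---- coordinates ----------------------------------------------------
  plan$cds_len <- ifelse(plan$orf_plan == "incomplete", 3L * n_cod,
                         3L * n_cod + 6L)
  plan$start <- rep(NA_integer_, nrow(plan))
  plan$end <- rep(NA_integer_, nrow(plan))
  plan$strand <- rep(NA_character_, nrow(plan))
  eve_scaffolds <- unique(plan$scaffold)
  for (scf in eve_scaffolds) {
    idx <- which(plan$scaffold == scf)
    idx <- idx[order(plan$slot[idx])]
    pos <- sample(500:1200, 1L)
    for (i in idx) {
      plan$start[i] <- pos
      plan$end[i] <- pos + plan$cds_len[i]
      plan$strand[i] <- sample(c("+", "-"), 1L)
      pos <- plan$end[i] + sample(1200:2200, 1L)
    }
    len <- pos + sample(2500:5000, 1L)
    add_scaffold(scf, plan$species[idx[1]], "eve", len)
  }
  for (sp in all_species) {
    for (k in seq_len(gp$n_busco_scaffolds))
      add_scaffold(next_scf(sp), sp, "busco", sample(6000:15000, 1L))
    for (k in seq_len(gp$n_host_scaffolds))
      add_scaffold(next_scf(sp), sp, "host", sample(6000:15000, 1L))
  }
  scaffolds <- do.call(rbind, scaffold_rows)
  plan$locus_id <- eve_locus_id(plan$scaffold, plan$start, plan$end,
                                plan$strand)
  plan$start_codon <- rep(NA_character_, nrow(plan))
  for (i in seq_len(nrow(plan)))
    plan$start_codon[i] <- .start_codon_for(plan$family[i], plan$species[i],
                                            config$start_codons)
  plan$start_codon[plan$orf_plan == "incomplete"] <- NA_character_

  ## ---- gene trees and alignments -------------------------------------
  fams <- sort(unique(plan$family))
  tip_ids <- stats::setNames(
    plan$locus_id, .plan_key(plan$event_id, plan$species, plan$family,
                             plan$copy))
  tree_paths <- character(0)
  aln_paths <- character(0)
  bodies <- stats::setNames(vector("list", nrow(plan)), plan$locus_id)
  for (fam in fams) {
    nwk <- simulate_gene_tree(fam, config$events, chrono$tree,
                              config$virus_panel, config$tree_noise,
                              config$orphans, tip_ids = tip_ids)
    tp <- file.path("trees", paste0(fam, ".nwk"))
    writeLines(nwk, file.path(out_dir, tp))
    tree_paths <- c(tree_paths, tp)
    fam_idx <- which(plan$family == fam)
    wasp_tips <- plan$locus_id[fam_idx]
    gt <- ape::read.tree(text = nwk)
    guide <- if (length(wasp_tips) > 1L) {
      pruned <- ape::keep.tip(gt, wasp_tips)
      pruned
    } else wasp_tips
    aln <- simulate_codon_alignment(guide, .omega_for(fam, op$omega),
                                    op$kappa, n_cod)
    for (i in fam_idx) {
      body <- unname(aln[plan$locus_id[i]])
      if (plan$orf_plan[i] == "premature_stop") body <- pseudogenize(body)
      bodies[[plan$locus_id[i]]] <- body
    }
    ap <- file.path("alignments", paste0(fam, ".fasta"))
    aln_out <- vapply(fam_idx, function(i) bodies[[plan$locus_id[i]]],
                      character(1))
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(stats::setNames(aln_out, plan$locus_id[fam_idx])),
      file.path(out_dir, ap))
    aln_paths <- c(aln_paths, ap)
  }
  ## BUSCO reference-gene alignments over the positive species
  busco_aln_paths <- character(0)
  if (length(positive) >= 2L) {
    guide <- ape::keep.tip(chrono$tree, positive)
    guide$edge.length <- guide$edge.length * 0.002
    for (k in 1:8) {
      aln <- simulate_codon_alignment(guide, 0.08, op$kappa, n_cod)
      bp <- file.path("alignments_busco", sprintf("busco%02d.fasta", k))
      Biostrings::writeXStringSet(
        Biostrings::DNAStringSet(aln), file.path(out_dir, bp))
      busco_aln_paths <- c(busco_aln_paths, bp)
    }
  }

  ## ---- scaffold sequences ---------------------------------------------
  .background <- function(len, gc) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
                 prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
          collapse = "")
  }
  scaffolds$gc_target <- pmin(0.6, pmax(0.2, stats::rnorm(
    nrow(scaffolds), gp$gc_mean, gp$gc_sd)))
  scaffolds$gc_target[scaffolds$type == "eve"] <-
    scaffolds$gc_target[scaffolds$type == "eve"] + gp$insert_gc_offset
  scaffolds$coverage <- round(pmax(1, stats::rnorm(
    nrow(scaffolds), gp$cov_mean, gp$cov_sd)), 2)
  fasta_paths <- character(0)
  for (sp in all_species) {
    rows <- scaffolds[scaffolds$species == sp, , drop = FALSE]
    seqs <- character(nrow(rows))
    for (r in seq_len(nrow(rows))) {
      s <- .background(rows$length[r], rows$gc_target[r])
      loci <- which(plan$scaffold == rows$scaffold[r])
      for (i in loci) {
        cds <- bodies[[plan$locus_id[i]]]
        if (plan$orf_plan[i] != "incomplete")
          cds <- paste0(plan$start_codon[i], cds, "TAA")
        if (plan$strand[i] == "-") cds <- .revcomp(cds)
        substr(s, plan$start[i] + 1L, plan$end[i]) <- cds
      }
      seqs[r] <- s
    }
    fp <- file.path("scaffolds", paste0(sp, ".fasta"))
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(stats::setNames(seqs, rows$scaffold)),
      file.path(out_dir, fp))
    fasta_paths <- c(fasta_paths, fp)
  }

  ## ---- hit tables ------------------------------------------------------
  hit_rows <- list()
  add_hit <- function(qseqid, sseqid, pident, len_aa, qstart, qend,
                      evalue, bitscore) {
    hit_rows[[length(hit_rows) + 1L]] <<- data.frame(
      qseqid = qseqid, sseqid = sseqid, pident = round(pident, 1),
      length = len_aa, mismatch = round(len_aa * (1 - pident / 100)),
      gapopen = sample(0:3, 1L), qstart = qstart, qend = qend,
      sstart = 1L, send = len_aa, evalue = evalue,
      bitscore = round(bitscore, 1), stringsAsFactors = FALSE)
  }
  vnames <- vapply(config$virus_panel, `[[`, character(1), "name")
  for (i in seq_len(nrow(plan))) {
    len_aa <- plan$cds_len[i] %/% 3L
    pid <- stats::runif(1, 45, 80)
    bs <- len_aa * 1.2 + stats::runif(1, 0, 25)
    q1 <- plan$start[i] + 1L
    q2 <- plan$end[i]
    if (plan$strand[i] == "-") { tmp <- q1; q1 <- q2; q2 <- tmp }
    add_hit(plan$scaffold[i],
            sprintf("%s|%s|p%02d", plan$donor_virus[i], plan$family[i],
                    sample(1:99, 1L)),
            pid, len_aa, q1, q2, 10^-stats::runif(1, 15, 70), bs)
    if (stats::runif(1) < 0.3) {
      ## secondary overlapping hit from a sister virus, lower score
      ov_start <- plan$start[i] + floor(plan$cds_len[i] * 0.2)
      ov_end <- plan$end[i] - floor(plan$cds_len[i] * 0.1)
      o1 <- ov_start + 1L
      o2 <- ov_end
      if (plan$strand[i] == "-") { tmp <- o1; o1 <- o2; o2 <- tmp }
      alt_virus <- setdiff(vnames, plan$donor_virus[i])[1]
      add_hit(plan$scaffold[i],
              sprintf("%s|%s|p%02d", alt_virus, plan$family[i],
                      sample(1:99, 1L)),
              pid - stats::runif(1, 5, 15), round(len_aa * 0.7),
              o1, o2, 10^-stats::runif(1, 8, 14), bs - stats::runif(1, 30, 60))
    }
  }
  ## decoy hits above the e-value ceiling, in gap regions of EVE scaffolds
  for (scf in eve_scaffolds[seq_along(eve_scaffolds) %% 3L == 0L]) {
    len <- scaffolds$length[scaffolds$scaffold == scf]
    add_hit(scf, sprintf("%s|%s|p%02d", sample(vnames, 1L),
                         "spurious", sample(1:99, 1L)),
            stats::runif(1, 30, 45), sample(40:90, 1L),
            len - 600L, len - 300L, stats::runif(1, 2e-3, 0.8),
            stats::runif(1, 20, 35))
  }
  viral_hits <- if (length(hit_rows)) do.call(rbind, hit_rows) else NULL
  .write_hits(viral_hits, file.path(out_dir, "viral_hits.tsv"))

  ## TE hits: half of the EVE scaffolds get one passing hit, plus rows
  ## failing the e-value or length filter
  hit_rows <- list()
  te_scafs <- eve_scaffolds[seq_along(eve_scaffolds) %% 2L == 0L]
  for (scf in te_scafs) {
    len <- scaffolds$length[scaffolds$scaffold == scf]
    p0 <- sample(50:400, 1L)
    laa <- sample(120:300, 1L)
    add_hit(scf, "RepPep|gypsy|rnd1", stats::runif(1, 50, 90), laa,
            p0 + 1L, p0 + 3L * laa, 10^-stats::runif(1, 12, 40),
            laa * 1.5)
    add_hit(scf, "RepPep|copia|rnd2", stats::runif(1, 40, 70),
            sample(40:90, 1L), p0 + 3L * laa + 200L,
            p0 + 3L * laa + 400L, 10^-stats::runif(1, 3, 9), 40)
  }
  .write_hits(if (length(hit_rows)) do.call(rbind, hit_rows) else NULL,
              file.path(out_dir, "te_hits.tsv"))

  ## ---- taxonomy, coverage, scaffold table, metadata -------------------
  tax_rows <- list()
  for (r in seq_len(nrow(scaffolds))) {
    scf <- scaffolds$scaffold[r]
    n_ins <- if (scaffolds$type[r] == "eve") sample(2:4, 1L) else
      sample(2:5, 1L)
    n_vir <- if (scaffolds$type[r] == "eve") sample(0:1, 1L) else 0L
    lab <- c(rep("insect", n_ins), rep("virus", n_vir))
    tax_rows[[r]] <- data.frame(
      scaffold = scf, protein_id = sprintf("%s_p%d", scf, seq_along(lab)),
      taxon = lab, stringsAsFactors = FALSE)
  }
  .write_tsv(do.call(rbind, tax_rows), file.path(out_dir, "taxonomy.tsv"))
  .write_tsv(data.frame(scaffold = scaffolds$scaffold,
                        mean_coverage = scaffolds$coverage),
             file.path(out_dir, "coverage.tsv"))
  .write_tsv(scaffolds[, c("scaffold", "species", "type", "length")],
             file.path(out_dir, "scaffolds.tsv"))
  writeLines(scaffolds$scaffold[scaffolds$type == "busco"],
             file.path(out_dir, "busco_scaffolds.txt"))
  virus_meta <- data.frame(
    tip = vnames, kind = "virus", species = vnames,
    lineage = vapply(config$virus_panel, `[[`, character(1), "lineage"),
    stringsAsFactors = FALSE)
  wasp_meta <- data.frame(tip = plan$locus_id,
                          kind = rep("wasp", nrow(plan)),
                          species = plan$species,
                          lineage = rep("", nrow(plan)),
                          stringsAsFactors = FALSE)
  .write_tsv(rbind(virus_meta, wasp_meta),
             file.path(out_dir, "tip_metadata.tsv"))
  panel_tab <- do.call(rbind, lapply(config$virus_panel, function(v)
    data.frame(virus = v$name, lineage = v$lineage,
               family = v$repertoire$family, core = v$repertoire$core,
               stringsAsFactors = FALSE)))
  .write_tsv(panel_tab, file.path(out_dir, "virus_panel.tsv"))
  writeLines(config$species_tree, file.path(out_dir, "chronogram.nwk"))

  ## ---- truth tables ----------------------------------------------------
  truth_loci <- plan[, c("locus_id", "species", "scaffold", "start", "end",
                         "strand", "family", "event_id", "copy",
                         "donor_virus", "start_codon")]
  truth_loci$orf_status <- plan$orf_plan
  .write_tsv(truth_loci, file.path(out_dir, "truth", "truth_loci.tsv"),
             version = "waspEVE-truth v1")
  truth_families <- .truth_families(config, plan)
  .write_tsv(truth_families, file.path(out_dir, "truth", "truth_families.tsv"),
             version = "waspEVE-truth v1")
  truth_events <- .truth_events(config, plan)
  .write_tsv(truth_events, file.path(out_dir, "truth", "truth_events.tsv"),
             version = "waspEVE-truth v1")

  manifest <- list(
    format = "waspEVE-dataset v1",
    seed = config$seed,
    species = all_species,
    positive_species = positive,
    n_loci = nrow(plan),
    n_families = length(fams),
    n_events = length(config$events),
    files = list(
      scaffolds = fasta_paths,
      scaffold_table = "scaffolds.tsv",
      coverage = "coverage.tsv",
      busco_scaffolds = "busco_scaffolds.txt",
      viral_hits = "viral_hits.tsv",
      te_hits = "te_hits.tsv",
      taxonomy = "taxonomy.tsv",
      trees = tree_paths,
      tip_metadata = "tip_metadata.tsv",
      virus_panel = "virus_panel.tsv",
      alignments = aln_paths,
      busco_alignments = busco_aln_paths,
      chronogram = "chronogram.nwk",
      truth_loci = "truth/truth_loci.tsv",
      truth_families = "truth/truth_families.tsv",
      truth_events = "truth/truth_events.tsv"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  structure(list(dir = out_dir, manifest = manifest,
                 truth_loci = truth_loci, truth_families = truth_families,
                 truth_events = truth_events, config = config),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("synthetic_dataset: %d loci, %d families, %d event(s) in %s\n",
              x$manifest$n_loci, x$manifest$n_families,
              x$manifest$n_events, x$dir))
  invisible(x)
}

.truth_families <- function(config, plan) {
  fams <- sort(unique(plan$family))
  rows <- lapply(fams, function(fam) {
    evs <- Filter(function(ev) {
      fam %in% ev$gene_families &&
        any(plan$family == fam & !is.na(plan$event_id) &
            plan$event_id == ev$event_id)
    }, config$events)
    lins <- vapply(evs, `[[`, character(1), "donor_lineage")
    unclass <- any(vapply(evs, function(ev)
      fam %in% ev$unclassifiable_families, logical(1)))
    orphan <- any(vapply(config$orphans, function(o) o$family == fam,
                         logical(1)))
    type <- if (unclass || orphan) "UNCLASSIFIED"
    else if (all(c("LhFV-like", "LbFV-like") %in% lins)) "TYPE_III"
    else if ("LhFV-like" %in% lins) "TYPE_I"
    else if ("LbFV-like" %in% lins) "TYPE_II"
    else "UNCLASSIFIED"
    data.frame(family = fam, true_type = type,
               events = paste(vapply(evs, `[[`, character(1), "event_id"),
                              collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

.truth_events <- function(config, plan) {
  rows <- lapply(config$events, function(ev) {
    sel <- !is.na(plan$event_id) & plan$event_id == ev$event_id
    data.frame(event_id = ev$event_id, donor_lineage = ev$donor_lineage,
               n_loci = sum(sel),
               n_families = length(unique(plan$family[sel])),
               families = paste(sort(unique(plan$family[sel])),
                                collapse = ","),
               species = paste(sort(unique(plan$species[sel])),
                               collapse = ","),
               stringsAsFactors = FALSE)
  })
  if (length(rows)) do.call(rbind, rows) else
    data.frame(event_id = character(0), donor_lineage = character(0),
               n_loci = integer(0), n_families = integer(0),
               families = character(0), species = character(0))
}

.write_tsv <- function(df, path, version = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(version)) writeLines(paste0("# ", version), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

.write_hits <- function(df, path) {
  if (is.null(df) || nrow(df) == 0L) {
    writeLines("# no hits", path)
    return(invisible())
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}
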