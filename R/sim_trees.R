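## Gene-tree simulation: a filamentovirus backbone with hytrosavirus
## outgroups, onto which each endogenization event grafts a wasp clade as
## sister to its donor-lineage virus. Internal labels are "aLRT/UFboot"
## strings; true clades draw ultrafast-bootstrap support from a high range,
## spurious (unclassifiable) clades from a low range.

.copies_for <- function(ev, family) {
  sp_present <- Filter(function(sp)
    !(family %in% (ev$losses[[sp]] %||% character(0))),
    ev$recipient_species)
  out <- list()
  for (sp in sp_present) {
    n <- 1L
    pc <- ev$paralog_counts
    if (nrow(pc)) {
      hit <- pc$n[pc$species == sp & pc$family == family]
      if (length(hit)) n <- hit[1]
    }
    out[[sp]] <- seq_len(n)
  }
  out
}

.support_label <- function(true, tn) {
  ub <- if (true) tn$true_ufboot else tn$spurious_ufboot
  al <- if (true) tn$true_alrt else tn$spurious_alrt
  vals <- seq(ub[1], ub[2])
  sprintf("%.1f/%d", stats::runif(1, al[1], al[2]),
          vals[sample.int(length(vals), 1L)])
}

.bl <- function(lo = 0.03, hi = 0.12) {
  sprintf("%.4f", stats::runif(1, lo, hi))
}

## Full labeled subtree string for >= 1 copies of one species (ladder).
.copy_ladder <- function(ids, tn, internal_true) {
  if (length(ids) == 1L) return(paste0(ids, ":", .bl(0.01, 0.06)))
  paste0("(", ids[1], ":", .bl(0.01, 0.06), ",",
         .copy_ladder(ids[-1], tn, internal_true), ")",
         .support_label(internal_true, tn), ":", .bl(0.01, 0.06))
}

## Wasp clade inner string (no outer label/branch; the caller attaches the
## clade's subtending support). copies: named list species -> copy ids.
.wasp_clade_inner <- function(copies, species_phylo, tn, internal_true) {
  sps <- names(copies)
  if (length(sps) == 1L) {
    ids <- copies[[1]]
    if (length(ids) == 1L) return(ids)
    return(paste0("(", ids[1], ":", .bl(0.01, 0.06), ",",
                  if (length(ids) == 2L)
                    paste0(ids[2], ":", .bl(0.01, 0.06))
                  else .copy_ladder(ids[-1], tn, internal_true), ")"))
  }
  sub <- ape::keep.tip(species_phylo, sps)
  ntip <- ape::Ntip(sub)
  rec <- function(node) {
    if (node <= ntip) {
      ids <- copies[[sub$tip.label[node]]]
      if (length(ids) == 1L) return(paste0(ids, ":", .bl()))
      return(paste0(.copy_ladder(ids, tn, internal_true)))
    }
    kids <- sub$edge[sub$edge[, 1] == node, 2]
    paste0("(", paste(vapply(kids, rec, character(1)), collapse = ","),
           ")", .support_label(internal_true, tn), ":", .bl())
  }
  root <- ntip + 1L
  kids <- sub$edge[sub$edge[, 1] == root, 2]
  paste0("(", paste(vapply(kids, rec, character(1)), collapse = ","), ")")
}

#' Simulate one gene-family phylogeny
#'
#' Builds a rooted newick with hytrosavirus outgroups, an other-filamentovirus
#' backbone, LhFV and LbFV tips, and one grafted wasp clade per event
#' containing the family, sister to the event's donor-lineage virus. Wasp
#' tips are named by `tip_ids` (named by `"event\\rspecies\\rfamily\\rcopy"`)
#' or default to `species|family|c<copy>` labels. Families listed in an
#' event's `unclassifiable_families` draw all wasp-clade supports from the
#' spurious range. Orphan families attach a single wasp tip inside an
#' other-FV clade.
#'
#' @param family Gene family name.
#' @param events List of [event_spec()]s.
#' @param species_tree Chronogram newick or `phylo` used for the wasp-clade
#'   topology.
#' @param virus_panel Virus panel (see [scenario_config()]).
#' @param tree_noise Support-range list (see [scenario_config()]).
#' @param orphans Orphan-locus list (see [scenario_config()]).
#' @param tip_ids Optional named character vector overriding wasp tip names.
#' @param seed Optional seed.
#' @return Newick string (one line, terminated by `;`).
#' @export
simulate_gene_tree <- function(family, events, species_tree, virus_panel,
                               tree_noise = list(), orphans = list(),
                               tip_ids = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tn <- utils::modifyList(list(
    true_ufboot = c(91L, 100L), spurious_ufboot = c(40L, 79L),
    true_alrt = c(85, 100), spurious_alrt = c(20, 80)), tree_noise)
  sp_phylo <- if (inherits(species_tree, "phylo")) species_tree else
    ape::read.tree(text = species_tree)
  lineages <- vapply(virus_panel, `[[`, character(1), "lineage")
  vnames <- vapply(virus_panel, `[[`, character(1), "name")
  in_rep <- vapply(virus_panel, function(v)
    family %in% v$repertoire$family, logical(1))
  ev_here <- Filter(function(ev) family %in% ev$gene_families, events)
  orphan_here <- Filter(function(o) o$family == family, orphans)
  if (!any(in_rep))
    stop("family '", family, "' absent from every virus repertoire")
  tipname <- function(ev_id, sp, copy) {
    key <- paste(ev_id, sp, family, copy, sep = "\r")
    if (!is.null(tip_ids) && key %in% names(tip_ids)) return(tip_ids[[key]])
    paste0(sp, "|", family, "|c", copy)
  }
  graft <- function(ev) {
    copies <- .copies_for(ev, family)
    if (length(copies) == 0L) return(NULL)
    for (sp in names(copies))
      copies[[sp]] <- vapply(copies[[sp]], function(cp)
        tipname(ev$event_id, sp, cp), character(1))
    truec <- !(family %in% ev$unclassifiable_families)
    inner <- .wasp_clade_inner(copies, sp_phylo, tn, internal_true = truec)
    n_tips <- sum(lengths(copies))
    if (n_tips == 1L) paste0(inner, ":", .bl(0.05, 0.2)) else
      paste0(inner, .support_label(truec, tn), ":", .bl(0.05, 0.2))
  }
  vb <- function() .bl(0.15, 0.6)
  og <- paste0("(GpSGHV:", vb(), ",MdSGHV:", vb(), ")",
               .support_label(TRUE, tn), ":", vb())
  if (length(orphan_here)) {
    o <- orphan_here[[1]]
    other <- setdiff(vnames[lineages == "other-FV"], o$donor_virus)[1]
    wtip <- tipname("orphan", o$species, 1L)
    core <- paste0("(", other, ":", vb(), ",(", o$donor_virus, ":", vb(),
                   ",", wtip, ":", .bl(0.05, 0.2), ")",
                   .support_label(TRUE, tn), ":", vb(), ")",
                   .support_label(TRUE, tn), ":", vb())
    return(paste0("(", og, ",", core, ");"))
  }
  w_anc <- w_rec <- NULL
  for (ev in ev_here) {
    g <- graft(ev)
    if (is.null(g)) next
    if (ev$donor_lineage == "LhFV-like") w_anc <- g else w_rec <- g
  }
  lh <- paste0("LhFV:", vb())
  lb <- paste0("LbFV:", vb())
  pair <- function(a, b) paste0("(", a, ",", b, ")",
                                .support_label(TRUE, tn), ":", vb())
  x <- if (!is.null(w_anc) && !is.null(w_rec)) {
    pair(pair(lh, w_anc), pair(lb, w_rec))
  } else if (!is.null(w_anc)) {
    pair(lb, pair(lh, w_anc))
  } else if (!is.null(w_rec)) {
    pair(lh, pair(lb, w_rec))
  } else {
    pair(lh, lb)
  }
  core <- paste0("(DfFV:", vb(), ",(CcFV:", vb(), ",", x, ")",
                 .support_label(TRUE, tn), ":", vb(), ")",
                 .support_label(TRUE, tn), ":", vb())
  paste0("(", og, ",", core, ");")
}
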