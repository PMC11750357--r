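## Grouping EVE loci into endogenization events: an evidence graph with
## colocation edges (same species, same scaffold) and homology-clade edges
## (same family, same supported wasp clade), whose connected components --
## found by union-find, i.e. the transitive closure of the colocation rule
## -- are the events.

#' Build the evidence graph over catalog loci
#'
#' Colocation edges join every pair of loci on the same scaffold of the
#' same species. Homology-clade edges join every pair of same-family loci
#' that sit in the same supported wasp clade of that family's topology
#' call (tree tips are locus ids); UNCLASSIFIED families contribute no
#' homology-clade edges.
#'
#' @param catalog EVE catalog data frame (locus_id, species, scaffold,
#'   family, ...).
#' @param topology_calls Named list of `topology_call` objects, one per
#'   family occurring in the catalog.
#' @return An `evidence_graph`: list with `nodes` (data frame: locus_id,
#'   family, species, scaffold, classified) and `edges` (data frame: from,
#'   to, type, provenance).
#' @export
build_graph <- function(catalog, topology_calls) {
  unknown <- setdiff(unique(catalog$family), names(topology_calls))
  if (length(unknown))
    stop("catalog loci reference families without topology calls: ",
         paste(unknown, collapse = ", "))
  types <- vapply(topology_calls, `[[`, character(1), "type")
  nodes <- data.frame(
    locus_id = catalog$locus_id, family = catalog$family,
    species = catalog$species, scaffold = catalog$scaffold,
    classified = types[catalog$family] != "UNCLASSIFIED",
    stringsAsFactors = FALSE, row.names = NULL)
  edges <- list()
  add_pairs <- function(ids, type, prov) {
    if (length(ids) < 2L) return(invisible())
    cmb <- utils::combn(sort(ids), 2)
    edges[[length(edges) + 1L]] <<- data.frame(
      from = cmb[1, ], to = cmb[2, ], type = type, provenance = prov,
      stringsAsFactors = FALSE)
  }
  for (key in unique(paste(catalog$species, catalog$scaffold, sep = "\r"))) {
    sel <- paste(catalog$species, catalog$scaffold, sep = "\r") == key
    add_pairs(catalog$locus_id[sel], "colocation",
              strsplit(key, "\r", fixed = TRUE)[[1]][2])
  }
  for (fam in unique(catalog$family)) {
    tc <- topology_calls[[fam]]
    if (tc$type == "UNCLASSIFIED") next
    fam_loci <- catalog$locus_id[catalog$family == fam]
    for (cl in tc$clades)
      add_pairs(intersect(cl$tips, fam_loci), "homology_clade", fam)
  }
  edges <- if (length(edges)) unique(do.call(rbind, edges)) else
    data.frame(from = character(0), to = character(0), type = character(0),
               provenance = character(0), stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges), class = "evidence_graph")
}

## Disjoint-set forest with path compression.
.union_find <- function(ids, from, to) {
  parent <- stats::setNames(seq_along(ids), ids)
  find <- function(i) {
    root <- i
    while (parent[root] != root) root <- parent[root]
    while (parent[i] != root) {
      nxt <- parent[i]
      parent[i] <<- root
      i <- nxt
    }
    root
  }
  for (k in seq_along(from)) {
    a <- find(match(from[k], ids))
    b <- find(match(to[k], ids))
    if (a != b) parent[a] <- b
  }
  vapply(seq_along(ids), find, integer(1))
}

#' Group loci into endogenization events
#'
#' Connected components of the evidence graph (the transitive closure of
#' colocation and homology-clade links: if A and B colocalize in one
#' species and B and C in another, A, B and C belong to one event).
#' Singleton components of loci whose family is UNCLASSIFIED are reported
#' as unassigned loci rather than events.
#'
#' @param graph An `evidence_graph` from [build_graph()].
#' @param topology_calls The calls used to build the graph (for donor
#'   lineages in the summaries).
#' @return List with `events` (list of event summaries, largest first; see
#'   [summarize_event()]) and `unassigned` (character vector of locus ids).
#' @export
group_events <- function(graph, topology_calls = NULL) {
  nodes <- graph$nodes
  if (nrow(nodes) == 0L) return(list(events = list(), unassigned = character(0)))
  comp <- .union_find(nodes$locus_id, graph$edges$from, graph$edges$to)
  events <- list()
  unassigned <- character(0)
  for (cid in unique(comp)) {
    members <- nodes[comp == cid, , drop = FALSE]
    if (nrow(members) == 1L && !members$classified[1]) {
      unassigned <- c(unassigned, members$locus_id[1])
    } else {
      events[[length(events) + 1L]] <-
        summarize_event(members, topology_calls)
    }
  }
  o <- order(-vapply(events, `[[`, integer(1), "n_loci"))
  events <- events[o]
  for (i in seq_along(events)) events[[i]]$event_id <- paste0("event_", i)
  list(events = events, unassigned = sort(unassigned))
}

#' Summarize one connected component as an endogenization event
#'
#' Gene families are deduplicated; the donor lineage is the majority over
#' the member families' nearest-viral-relative tags (taken from the clade
#' of each family's call that contains the member loci); a conflict flag is
#' set when member families disagree on the donor lineage -- phylogenetic
#' congruence within an event is checked, never assumed.
#'
#' @param members Data frame of member nodes (locus_id, family, species).
#' @param topology_calls Named list of `topology_call` objects (optional;
#'   without it donor lineage is `NA`).
#' @return List: `event_id`, `loci`, `n_loci`, `families`, `species`,
#'   `donor_lineage`, `family_lineages`, `conflict`.
#' @export
summarize_event <- function(members, topology_calls = NULL) {
  fam_lineage <- character(0)
  if (!is.null(topology_calls)) {
    for (fam in unique(members$family)) {
      tc <- topology_calls[[fam]]
      if (is.null(tc) || tc$type == "UNCLASSIFIED") next
      fam_loci <- members$locus_id[members$family == fam]
      tags <- unique(unlist(lapply(tc$clades, function(cl)
        if (any(fam_loci %in% cl$tips)) cl$nearest_lineage else NULL)))
      if (length(tags))
        fam_lineage[fam] <- if (length(tags) == 1L) tags else "conflict"
    }
  }
  tags <- fam_lineage[fam_lineage != "conflict"]
  donor <- if (length(tags)) {
    tab <- sort(table(tags), decreasing = TRUE)
    names(tab)[1]
  } else NA_character_
  conflict <- length(unique(fam_lineage)) > 1L
  list(event_id = NA_character_,
       loci = sort(members$locus_id), n_loci = nrow(members),
       families = sort(unique(members$family)),
       species = sort(unique(members$species)),
       donor_lineage = donor,
       family_lineages = fam_lineage,
       conflict = conflict)
}

#' Species-by-family presence matrix with ORF annotations
#'
#' The tabular analogue of a domestication heatmap: one row per species,
#' one column per viral gene family. Cells show the copy number when
#' greater than 1, `#` when any copy uses an alternative (non-ATG) start,
#' `*` when every copy has a premature stop or incomplete ORF, and `(*)`
#' when only some copies do.
#'
#' @param catalog EVE catalog with `orf_status` and `start_codon` columns.
#' @return Character matrix (species x family); empty string marks absence.
#' @export
presence_matrix <- function(catalog) {
  species <- sort(unique(catalog$species))
  fams <- sort(unique(catalog$family))
  m <- matrix("", length(species), length(fams),
              dimnames = list(species, fams))
  for (sp in species) {
    for (fam in fams) {
      rows <- catalog[catalog$species == sp & catalog$family == fam, ,
                      drop = FALSE]
      n <- nrow(rows)
      if (n == 0L) next
      cell <- "+"
      if (n > 1L) cell <- as.character(n)
      bad <- rows$orf_status %in% c("premature_stop", "incomplete")
      if (all(bad)) cell <- paste0(cell, "*")
      else if (any(bad)) cell <- paste0(cell, "(*)")
      if (any(!is.na(rows$start_codon) & rows$start_codon != "ATG" & !bad))
        cell <- paste0(cell, "#")
      m[sp, fam] <- cell
    }
  }
  m
}
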