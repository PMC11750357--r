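## Gene-tree topology classification: support parsing from "aLRT/UFboot"
## labels, outgroup-else-midpoint rooting, supported wasp-only monophyly,
## nearest viral relatives, and the type I / II / III call.

#' Parse an "aLRT/UFboot" support label
#'
#' Dual labels like `"97.3/100"` yield the second (ultrafast bootstrap)
#' component; single-number labels yield that number; empty labels yield
#' `NA`. Non-numeric labels are an error.
#'
#' @param label Character vector of node labels.
#' @return Numeric vector of supports (`NA` where absent).
#' @export
parse_support <- function(label) {
  vapply(label, function(l) {
    if (is.na(l) || !nzchar(l) || identical(l, "Root")) return(NA_real_)
    parts <- strsplit(l, "/", fixed = TRUE)[[1]]
    val <- suppressWarnings(as.numeric(parts[length(parts)]))
    if (is.na(val)) stop("cannot parse support label: '", l, "'")
    val
  }, numeric(1), USE.NAMES = FALSE)
}

#' Read tip metadata
#'
#' Tab-separated table with columns `tip`, `kind` (`wasp` or `virus`),
#' `species`, `lineage` (viral lineage tag, e.g. `LhFV-like`, `LbFV-like`,
#' `other`, `outgroup`; empty for wasps).
#'
#' @param path TSV path.
#' @return Data frame.
#' @export
read_tip_metadata <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  req <- c("tip", "kind", "species", "lineage")
  if (!all(req %in% names(df)))
    stop("tip metadata must have columns ", paste(req, collapse = ", "))
  df
}

.meta_lookup <- function(metadata, tips, field) {
  idx <- match(tips, metadata$tip)
  if (anyNA(idx)) stop("tips missing from metadata: ",
                       paste(tips[is.na(idx)], collapse = ", "))
  metadata[[field]][idx]
}

#' Root a gene tree for classification
#'
#' Roots on the outgroup-tagged tips (lineage `"outgroup"`, e.g.
#' hytrosavirus sequences) when present; otherwise midpoint-roots. Support
#' labels are treated as edge labels so they stay attached to the correct
#' bipartitions across re-rooting.
#'
#' @param tree An `ape::phylo`.
#' @param metadata Tip metadata (see [read_tip_metadata()]).
#' @return A rooted `phylo`.
#' @export
root_for_classification <- function(tree, metadata) {
  if (ape::Ntip(tree) < 3L) stop("tree has fewer than 3 tips")
  og <- metadata$tip[metadata$kind == "virus" & metadata$lineage == "outgroup"]
  og <- intersect(og, tree$tip.label)
  rooted <- NULL
  if (length(og)) {
    rooted <- tryCatch(
      ape::root(tree, outgroup = og, resolve.root = TRUE, edgelabel = TRUE),
      error = function(e) NULL)
  }
  if (is.null(rooted))
    rooted <- phangorn::midpoint(tree, node.labels = "support")
  if (!is.null(rooted$node.label))
    rooted$node.label[rooted$node.label == "Root"] <- ""
  rooted
}

.children <- function(tree, node) tree$edge[tree$edge[, 1] == node, 2]
.parent <- function(tree, node) {
  p <- tree$edge[tree$edge[, 2] == node, 1]
  if (length(p)) p else NA_integer_
}
.clade_tips <- function(tree, node) {
  ntip <- ape::Ntip(tree)
  if (node <= ntip) return(tree$tip.label[node])
  ape::extract.clade(tree, node)$tip.label
}
.node_support <- function(tree, node) {
  ntip <- ape::Ntip(tree)
  if (node <= ntip || is.null(tree$node.label)) return(NA_real_)
  parse_support(tree$node.label[node - ntip])
}

#' Maximal supported wasp-only clades
#'
#' Finds maximal monophyletic all-wasp clades whose subtending-branch
#' support strictly exceeds `min_support`; all-wasp clades failing the
#' threshold are decomposed into their supported sub-clades, down to
#' singleton wasp tips, which are admissible clades with vacuously
#' sufficient support.
#'
#' @param tree Rooted `phylo` (see [root_for_classification()]).
#' @param metadata Tip metadata.
#' @param min_support Strict support threshold (default 80, ultrafast
#'   bootstrap component).
#' @return List of clades, each a list with `node`, `tips`, `species`,
#'   `support`, `n_tips`.
#' @export
wasp_clades <- function(tree, metadata, min_support = 80) {
  ntip <- ape::Ntip(tree)
  kind <- stats::setNames(.meta_lookup(metadata, tree$tip.label, "kind"),
                          tree$tip.label)
  clades <- list()
  emit <- function(node) {
    tips <- .clade_tips(tree, node)
    clades[[length(clades) + 1L]] <<- list(
      node = node, tips = tips,
      species = unique(.meta_lookup(metadata, tips, "species")),
      support = .node_support(tree, node), n_tips = length(tips))
  }
  walk <- function(node) {
    tips <- .clade_tips(tree, node)
    if (all(kind[tips] == "wasp")) {
      if (node <= ntip) {
        emit(node)
        return(invisible())
      }
      sup <- .node_support(tree, node)
      if (is.finite(sup) && sup > min_support) {
        emit(node)
        return(invisible())
      }
      ## all-wasp but unsupported: decompose
      for (ch in .children(tree, node)) walk(ch)
    } else if (node > ntip) {
      for (ch in .children(tree, node)) walk(ch)
    }
  }
  walk(ntip + 1L)
  clades
}

#' Nearest viral relative of a wasp clade
#'
#' Lineage tag of the majority of virus tips in the clade's sister group;
#' when the sister contains no virus tips the search walks toward the root
#' to the first virus-containing sister (recorded in the result).
#'
#' @param tree Rooted `phylo`.
#' @param metadata Tip metadata.
#' @param clade A clade from [wasp_clades()] (or a node number).
#' @return List with `lineage`, `walked` (logical), `virus_tips`.
#' @export
nearest_viral_relative <- function(tree, metadata, clade) {
  node <- if (is.list(clade)) clade$node else clade
  kind <- stats::setNames(.meta_lookup(metadata, tree$tip.label, "kind"),
                          tree$tip.label)
  if (!any(kind == "virus")) stop("tree contains no virus tips")
  walked <- FALSE
  cur <- node
  repeat {
    p <- .parent(tree, cur)
    if (is.na(p)) stop("reached root without finding a virus-containing sister")
    sibs <- setdiff(.children(tree, p), cur)
    sib_tips <- unlist(lapply(sibs, .clade_tips, tree = tree))
    vt <- sib_tips[kind[sib_tips] == "virus"]
    if (length(vt)) {
      lin <- .meta_lookup(metadata, vt, "lineage")
      tab <- sort(table(lin), decreasing = TRUE)
      return(list(lineage = names(tab)[1], walked = walked, virus_tips = vt))
    }
    walked <- TRUE
    cur <- p
  }
}

#' Classify a gene-family phylogeny into topology types
#'
#' Type I: a single supported wasp clade containing every wasp tip, with an
#' LhFV-like nearest viral relative (the ancestral, multi-species event
#' signature). Type II: the only wasp presence is a single-species clade
#' (typically one *Rhoptromeris* sequence) with an LbFV-like nearest
#' relative. Type III: both patterns co-occur in one tree. Everything else
#' -- unsupported wasp clades, nearest relatives outside the two canonical
#' lineages, or clade configurations not matching the three patterns -- is
#' UNCLASSIFIED, with the reason in `notes`.
#'
#' @param tree `ape::phylo` (rooted internally via
#'   [root_for_classification()]).
#' @param metadata Tip metadata.
#' @param min_support Strict support threshold (default 80).
#' @param family Optional family label.
#' @param ancestral_lineage,recent_lineage Canonical donor lineage tags.
#' @return A `topology_call`: list with `family`, `type`, `clades` (each
#'   with tips, species, support, nearest lineage), `notes`.
#' @export
classify_gene_tree <- function(tree, metadata, min_support = 80,
                               family = NA_character_,
                               ancestral_lineage = "LhFV-like",
                               recent_lineage = "LbFV-like") {
  rooted <- root_for_classification(tree, metadata)
  kind <- .meta_lookup(metadata, rooted$tip.label, "kind")
  notes <- character(0)
  call <- function(type) {
    structure(list(family = family, type = type, clades = clades,
                   notes = notes), class = "topology_call")
  }
  wasp_tips <- rooted$tip.label[kind == "wasp"]
  clades <- list()
  if (length(wasp_tips) == 0L) {
    notes <- "no wasp tips"
    return(call("UNCLASSIFIED"))
  }
  if (!any(kind == "virus")) {
    notes <- "no viral context"
    return(call("UNCLASSIFIED"))
  }
  clades <- wasp_clades(rooted, metadata, min_support)
  for (i in seq_along(clades)) {
    nv <- nearest_viral_relative(rooted, metadata, clades[[i]])
    clades[[i]]$nearest_lineage <- nv$lineage
    clades[[i]]$walked <- nv$walked
  }
  lineages <- vapply(clades, `[[`, character(1), "nearest_lineage")
  covered <- sort(unlist(lapply(clades, `[[`, "tips")))
  covers_all <- identical(covered, sort(wasp_tips))
  off_canon <- !(lineages %in% c(ancestral_lineage, recent_lineage))
  if (any(off_canon)) {
    lineages[off_canon] <- "other"
    for (i in which(off_canon)) clades[[i]]$nearest_lineage <- "other"
    notes <- c(notes, "nearest relative outside canonical lineages")
    return(call("UNCLASSIFIED"))
  }
  n_anc <- sum(lineages == ancestral_lineage)
  n_rec <- sum(lineages == recent_lineage)
  single_species <- vapply(clades, function(cl)
    length(cl$species) == 1L, logical(1))
  if (length(clades) == 1L && covers_all && n_anc == 1L)
    return(call("TYPE_I"))
  if (length(clades) == 1L && covers_all && n_rec == 1L) {
    if (single_species[1]) return(call("TYPE_II"))
    notes <- c(notes, "recent-lineage clade spans multiple species")
    return(call("UNCLASSIFIED"))
  }
  if (length(clades) == 2L && covers_all && n_anc == 1L && n_rec == 1L) {
    if (single_species[which(lineages == recent_lineage)])
      return(call("TYPE_III"))
    notes <- c(notes, "recent-lineage clade spans multiple species")
    return(call("UNCLASSIFIED"))
  }
  notes <- c(notes, sprintf(
    "clade pattern outside the three types (%d ancestral-adjacent, %d recent-adjacent, all tips covered: %s)",
    n_anc, n_rec, covers_all))
  call("UNCLASSIFIED")
}

#' @export
print.topology_call <- function(x, ...) {
  cat(sprintf("topology_call%s: %s (%d wasp clade(s))\n",
              if (is.na(x$family)) "" else paste0(" [", x$family, "]"),
              x$type, length(x$clades)))
  for (cl in x$clades)
    cat(sprintf("  clade n=%d support=%s nearest=%s species=%s\n",
                cl$n_tips, format(cl$support), cl$nearest_lineage %||% "?",
                paste(cl$species, collapse = ",")))
  if (length(x$notes)) cat("  notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Tabular summary of topology calls
#'
#' @param calls List of `topology_call` objects.
#' @return Data frame with one row per call.
#' @export
topology_call_table <- function(calls) {
  do.call(rbind, lapply(calls, function(x) {
    data.frame(
      family = x$family, type = x$type, n_clades = length(x$clades),
      clade_members = paste(vapply(x$clades, function(cl)
        paste(cl$tips, collapse = ","), character(1)), collapse = ";"),
      supports = paste(vapply(x$clades, function(cl)
        format(cl$support), character(1)), collapse = ";"),
      nearest = paste(vapply(x$clades, function(cl)
        cl$nearest_lineage %||% NA_character_, character(1)), collapse = ";"),
      notes = paste(x$notes, collapse = "; "),
      stringsAsFactors = FALSE)
  }))
}
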