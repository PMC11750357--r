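## Chromosomal-integration evidence for candidate scaffolds: GC/coverage
## envelopes built from BUSCO-containing scaffolds, majority-vote contig
## taxonomy over predicted proteins, and merged transposable-element hits.

#' GC fraction of a nucleotide sequence
#'
#' (G + C) / (A + C + G + T); ambiguity codes (N etc.) are excluded from
#' both numerator and denominator.
#'
#' @param sequence A nucleotide string (or coercible via `as.character`).
#' @return GC fraction in `[0, 1]`.
#' @export
gc_content <- function(sequence) {
  s <- toupper(as.character(sequence))
  if (nchar(s) == 0L) stop("empty sequence")
  counts <- table(strsplit(s, "")[[1]])
  acgt <- sum(counts[intersect(names(counts), c("A", "C", "G", "T"))])
  if (acgt == 0L) stop("sequence has no unambiguous bases; GC undefined")
  gc <- sum(counts[intersect(names(counts), c("G", "C"))])
  gc / acgt
}

#' Robust acceptance envelope from BUSCO scaffolds
#'
#' For each metric (GC, coverage) the acceptance interval is
#' `median +/- k * MAD` over the BUSCO-containing scaffolds, with MAD the
#' raw median absolute deviation (no normal-consistency constant). With
#' zero spread the interval degenerates to a point.
#'
#' @param busco_records Data frame with columns `gc` and `coverage`, one
#'   row per BUSCO scaffold (at least 5 rows).
#' @param k Envelope half-width in MAD units (default 5).
#' @return List with `gc` and `coverage`, each `c(lo, hi)`, plus `k`.
#' @export
busco_envelope <- function(busco_records, k = 5) {
  if (!is.data.frame(busco_records) ||
      !all(c("gc", "coverage") %in% names(busco_records)))
    stop("busco_records must have columns gc and coverage")
  if (nrow(busco_records) < 5L)
    stop("insufficient reference: need >= 5 BUSCO scaffolds, got ",
         nrow(busco_records))
  ivl <- function(x) {
    m <- stats::median(x)
    mad <- stats::mad(x, constant = 1)
    c(m - k * mad, m + k * mad)
  }
  list(gc = ivl(busco_records$gc),
       coverage = ivl(busco_records$coverage), k = k)
}

#' Majority-vote taxonomy for a scaffold
#'
#' Assigns the strict-majority taxon among the taxonomic labels of a
#' scaffold's predicted proteins; ties and empty inputs give
#' `"unassigned"` (conservative: no false eukaryotic assignment).
#'
#' @param labels Character vector of taxon labels (may be empty).
#' @return A single taxon label or `"unassigned"`.
#' @export
majority_vote_taxonomy <- function(labels) {
  labels <- labels[!is.na(labels) & nzchar(labels)]
  if (length(labels) == 0L) return("unassigned")
  tab <- sort(table(labels), decreasing = TRUE)
  if (length(tab) > 1L && tab[1] == tab[2]) return("unassigned")
  if (tab[1] * 2L <= length(labels)) return("unassigned")
  names(tab)[1]
}

#' Filtered, merged transposable-element intervals for one scaffold
#'
#' Keeps hits with e-value strictly below `e_max` and alignment length
#' strictly above `len_min` amino acids, then merges overlapping intervals
#' under 0-based half-open coordinates; book-ended intervals
#' (`end == start`) are treated as overlapping. Intervals are
#' strand-agnostic and returned sorted by start.
#'
#' @param hits Data frame of tabular hits for one scaffold with columns
#'   `qstart`, `qend` (scaffold coordinates, 0-based half-open after
#'   normalization; 1-based inclusive pairs with `qstart > qend` are
#'   normalized at entry), `evalue`, `length` (aa).
#' @param e_max Exclusive e-value ceiling (default 1e-10).
#' @param len_min Exclusive alignment-length floor in aa (default 100).
#' @return Data frame with columns `start`, `end` (0-based half-open),
#'   sorted, pairwise disjoint.
#' @export
te_intervals <- function(hits, e_max = 1e-10, len_min = 100) {
  req <- c("qstart", "qend", "evalue", "length")
  if (!is.data.frame(hits) || !all(req %in% names(hits)))
    stop("hits must be a data frame with columns ",
         paste(req, collapse = ", "))
  bad <- which(!is.finite(hits$qstart) | !is.finite(hits$qend) |
               !is.finite(hits$evalue) | !is.finite(hits$length))
  if (length(bad))
    stop("malformed TE hit row(s): ", paste(bad, collapse = ", "))
  keep <- hits$evalue < e_max & hits$length > len_min
  hits <- hits[keep, , drop = FALSE]
  if (nrow(hits) == 0L)
    return(data.frame(start = integer(0), end = integer(0)))
  start <- pmin(hits$qstart, hits$qend)
  end <- pmax(hits$qstart, hits$qend)
  merge_intervals(data.frame(start = start, end = end))
}

#' Merge possibly-overlapping half-open intervals
#'
#' Book-ended intervals (end == next start) are merged.
#' @param ivls Data frame with `start`, `end`.
#' @return Sorted data frame of disjoint intervals.
#' @export
merge_intervals <- function(ivls) {
  if (nrow(ivls) == 0L) return(ivls)
  o <- order(ivls$start, ivls$end)
  s <- ivls$start[o]
  e <- ivls$end[o]
  out_s <- s[1]
  out_e <- e[1]
  for (i in seq_along(s)[-1]) {
    j <- length(out_s)
    if (s[i] <= out_e[j]) {
      out_e[j] <- max(out_e[j], e[i])
    } else {
      out_s <- c(out_s, s[i])
      out_e <- c(out_e, e[i])
    }
  }
  data.frame(start = out_s, end = out_e)
}

#' Integration-evidence verdict for one scaffold
#'
#' A scaffold is called `endogenized` when its GC and coverage both fall in
#' the BUSCO envelope, or it carries at least one eukaryotic predicted gene
#' (counted over `eukaryotic_taxa`), or at least one filtered TE interval.
#' With none of these it is `likely_exogenous`; `ambiguous` is reserved for
#' scaffolds whose GC or coverage is missing and that carry no gene/TE
#' evidence.
#'
#' @param record One-row data frame (or list) with `scaffold`, `gc`,
#'   `coverage`.
#' @param envelope A [busco_envelope()] result.
#' @param gene_labels Taxon labels of the scaffold's predicted proteins.
#' @param te_hits TE hit data frame for this scaffold (see
#'   [te_intervals()]), or `NULL`.
#' @param eukaryotic_taxa Labels counted as eukaryotic (default
#'   `c("insect", "eukaryote")`).
#' @return One-row data frame: `scaffold`, `gc_ok`, `coverage_ok`,
#'   `n_eukaryotic_genes`, `n_te_intervals`, `contig_taxon`, `verdict`.
#' @export
classify_scaffold <- function(record, envelope, gene_labels = character(0),
                              te_hits = NULL,
                              eukaryotic_taxa = c("insect", "eukaryote")) {
  gc_ok <- record$gc >= envelope$gc[1] & record$gc <= envelope$gc[2]
  coverage_ok <- record$coverage >= envelope$coverage[1] &
    record$coverage <= envelope$coverage[2]
  n_euk <- sum(gene_labels %in% eukaryotic_taxa)
  n_te <- if (is.null(te_hits)) 0L else nrow(te_intervals(te_hits))
  taxon <- majority_vote_taxonomy(gene_labels)
  verdict <- if (isTRUE(gc_ok && coverage_ok) || n_euk >= 1L || n_te >= 1L) {
    "endogenized"
  } else if (is.na(gc_ok) || is.na(coverage_ok)) {
    "ambiguous"
  } else {
    "likely_exogenous"
  }
  data.frame(scaffold = record$scaffold, gc_ok = gc_ok,
             coverage_ok = coverage_ok, n_eukaryotic_genes = n_euk,
             n_te_intervals = n_te, contig_taxon = taxon,
             verdict = verdict, stringsAsFactors = FALSE)
}
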