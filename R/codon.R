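## Codon-level machinery shared by the Nei-Gojobori estimator and the
## codon-evolution simulator: sense-codon tables, per-codon synonymous site
## fractions, and pathway-averaged difference matrices.

.weve <- new.env(parent = emptyenv())

#' Standard genetic code keyed by codon
#' @noRd
.genetic_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
}

#' The 61 sense codons in fixed lexicographic order
#' @noRd
sense_codons <- function() {
  if (is.null(.weve$sense)) {
    gc <- .genetic_code()
    .weve$sense <- sort(names(gc)[gc != "*"])
  }
  .weve$sense
}

.is_stop <- function(codon) {
  gc <- .genetic_code()
  unname(gc[codon] == "*")
}

.NUC <- c("A", "C", "G", "T")

.is_transition <- function(a, b) {
  (a %in% c("A", "G") && b %in% c("A", "G")) ||
    (a %in% c("C", "T") && b %in% c("C", "T"))
}

## Per-codon count of synonymous sites: at each of the three positions the
## fraction of the three possible single-nucleotide changes that preserve the
## amino acid.  Changes to stop codons count as nonsynonymous so that
## S + N = 3 exactly for every codon.
.syn_sites_one <- function(codon, gc) {
  aa <- gc[codon]
  s <- 0
  for (pos in 1:3) {
    base <- substr(codon, pos, pos)
    for (alt in setdiff(.NUC, base)) {
      mut <- codon
      substr(mut, pos, pos) <- alt
      if (gc[mut] == aa) s <- s + 1 / 3
    }
  }
  s
}

#' Synonymous-site counts for all sense codons (named vector)
#' @noRd
ng_syn_sites <- function() {
  if (is.null(.weve$syn_sites)) {
    gc <- .genetic_code()
    sc <- sense_codons()
    .weve$syn_sites <- stats::setNames(
      vapply(sc, .syn_sites_one, numeric(1), gc = gc), sc)
  }
  .weve$syn_sites
}

## Average synonymous/nonsynonymous differences between two sense codons over
## all minimal mutational pathways; pathways passing through a stop codon are
## excluded.  If every pathway is blocked by stops (does not occur for sense
## codon pairs under the standard code, but guarded anyway) stop-crossing
## pathways are used with stop steps counted as nonsynonymous.
.pathway_diffs <- function(c1, c2, gc) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  k <- length(pos)
  if (k == 0L) return(c(sd = 0, nd = 0))
  perms <- switch(as.character(k),
    "1" = list(pos),
    "2" = list(pos, rev(pos)),
    "3" = lapply(list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1)),
                 function(o) pos[o]))
  walk <- function(order, allow_stop) {
    cur <- c1
    sd <- nd <- 0
    for (p in order) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (!allow_stop && gc[nxt] == "*") return(NULL)
      if (gc[cur] == gc[nxt] && gc[nxt] != "*") sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd = sd, nd = nd)
  }
  res <- Filter(Negate(is.null), lapply(perms, walk, allow_stop = FALSE))
  if (length(res) == 0L) res <- lapply(perms, walk, allow_stop = TRUE)
  m <- do.call(rbind, res)
  c(sd = mean(m[, "sd"]), nd = mean(m[, "nd"]))
}

#' Pathway-averaged difference matrices (61 x 61), cached
#' @noRd
ng_diff_matrices <- function() {
  if (is.null(.weve$diff_sd)) {
    gc <- .genetic_code()
    sc <- sense_codons()
    n <- length(sc)
    sd_m <- nd_m <- matrix(0, n, n, dimnames = list(sc, sc))
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (j <= i) next
        d <- .pathway_diffs(sc[i], sc[j], gc)
        sd_m[i, j] <- sd_m[j, i] <- d["sd"]
        nd_m[i, j] <- nd_m[j, i] <- d["nd"]
      }
    }
    .weve$diff_sd <- sd_m
    .weve$diff_nd <- nd_m
  }
  list(sd = .weve$diff_sd, nd = .weve$diff_nd)
}

#' Split a nucleotide string into codons
#' @noRd
split_codons <- function(seq) {
  seq <- toupper(as.character(seq))
  n <- nchar(seq)
  if (n %% 3L != 0L) stop("sequence length ", n, " is not a multiple of 3")
  substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' Jukes-Cantor distance from a proportion of differences
#'
#' Returns `NA` when the proportion reaches or exceeds 3/4 (correction
#' undefined).
#' @noRd
jc_correct <- function(p) {
  ifelse(p < 0.75, -0.75 * log(1 - 4 * p / 3), NA_real_)
}
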