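## From raw viral-protein homology hits to an EVE catalog: 12-column tabular
## parsing with strand normalization, e-value filtering, same-strand interval
## union into loci, and ORF-integrity calls.

#' Read 12-column tabular homology hits
#'
#' Standard BLAST/MMseqs2 tabular format (qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore), comment lines
#' (`#`) tolerated. Query coordinates are 1-based inclusive in the file;
#' hits with `qstart > qend` are minus-strand and are normalized at parse
#' time to 0-based half-open forward-strand coordinates with `strand = "-"`.
#' Subject ids of the form `virus|family|protein` carry the viral gene
#' family and source virus, which are split into columns.
#'
#' @param path Path to the tabular file.
#' @return Data frame with the 12 columns plus `start`, `end` (0-based
#'   half-open), `strand`, `subject_virus`, `family`.
#' @export
read_hits <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  df <- tryCatch(
    utils::read.table(path, sep = "\t", comment.char = "#",
                      col.names = cols, stringsAsFactors = FALSE),
    error = function(e) {
      ## tolerate empty hit tables (comment-only or zero-length files)
      if (grepl("no lines available", conditionMessage(e))) {
        empty <- c(rep(list(character(0)), 2), rep(list(numeric(0)), 10))
        names(empty) <- cols
        return(as.data.frame(empty, stringsAsFactors = FALSE))
      }
      stop(e)
    })
  if (nrow(df) == 0L) {
    empty <- c(rep(list(character(0)), 2), rep(list(numeric(0)), 10))
    names(empty) <- cols
    df <- as.data.frame(empty, stringsAsFactors = FALSE)
  }
  normalize_hits(df)
}

#' @rdname read_hits
#' @param hits Data frame already carrying the 12 tabular columns.
#' @export
normalize_hits <- function(hits) {
  if (any(hits$evalue < 0)) stop("negative e-value in hit table")
  hits$strand <- ifelse(hits$qstart <= hits$qend, "+", "-")
  lo <- pmin(hits$qstart, hits$qend)
  hi <- pmax(hits$qstart, hits$qend)
  hits$start <- lo - 1L   # 0-based half-open
  hits$end <- hi
  parts <- strsplit(hits$sseqid, "|", fixed = TRUE)
  hits$subject_virus <- vapply(parts, `[`, character(1), 1L)
  hits$family <- vapply(parts, function(p)
    if (length(p) >= 2L) p[2] else NA_character_, character(1))
  hits
}

#' Filter hits by e-value ceiling
#'
#' Keeps hits with e-value less than or equal to `e_max` ("max" read as
#' inclusive); input order preserved.
#'
#' @param hits Hit data frame (see [read_hits()]).
#' @param e_max Inclusive e-value ceiling (default 1e-3).
#' @return Filtered data frame.
#' @export
filter_hits <- function(hits, e_max = 1e-3) {
  stopifnot(e_max > 0)
  hits[hits$evalue <= e_max, , drop = FALSE]
}

#' Call EVE loci from filtered hits
#'
#' Overlapping same-scaffold same-strand hits are merged into one locus by
#' interval union regardless of family; the locus family (and source virus)
#' are those of the highest-bitscore constituent hit, ties broken by lower
#' e-value then lexicographic subject id.
#'
#' @param hits Filtered, normalized hit data frame.
#' @param species Optional named character vector mapping scaffold id to
#'   species, or a single species label.
#' @return Data frame (EVE catalog rows): `locus_id`, `species`,
#'   `scaffold`, `start`, `end`, `strand`, `family`, `best_virus`,
#'   `n_hits`, `best_bitscore`.
#' @export
call_loci <- function(hits, species = NA_character_) {
  if (nrow(hits) == 0L)
    return(data.frame(locus_id = character(0), species = character(0),
                      scaffold = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      family = character(0), best_virus = character(0),
                      n_hits = integer(0), best_bitscore = numeric(0),
                      stringsAsFactors = FALSE))
  sp_of <- function(scaffold) {
    if (length(species) == 1L && is.null(names(species))) return(species)
    out <- unname(species[scaffold])
    ifelse(is.na(out), NA_character_, out)
  }
  out <- list()
  for (key in unique(paste(hits$qseqid, hits$strand, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    h <- hits[hits$qseqid == parts[1] & hits$strand == parts[2], , drop = FALSE]
    h <- h[order(h$start, h$end), , drop = FALSE]
    grp <- integer(nrow(h))
    g <- 1L
    cur_end <- h$end[1]
    grp[1] <- g
    for (i in seq_len(nrow(h))[-1]) {
      if (h$start[i] < cur_end) {          # strict overlap merges loci
        grp[i] <- g
        cur_end <- max(cur_end, h$end[i])
      } else {
        g <- g + 1L
        grp[i] <- g
        cur_end <- h$end[i]
      }
    }
    for (gi in seq_len(g)) {
      hh <- h[grp == gi, , drop = FALSE]
      best <- hh[order(-hh$bitscore, hh$evalue, hh$sseqid), , drop = FALSE][1, ]
      s <- min(hh$start)
      e <- max(hh$end)
      out[[length(out) + 1L]] <- data.frame(
        locus_id = eve_locus_id(parts[1], s, e, parts[2]),
        species = sp_of(parts[1]), scaffold = parts[1],
        start = s, end = e, strand = parts[2],
        family = best$family, best_virus = best$subject_virus,
        n_hits = nrow(hh), best_bitscore = best$bitscore,
        stringsAsFactors = FALSE)
    }
  }
  cat_df <- do.call(rbind, out)
  cat_df[order(cat_df$scaffold, cat_df$start, cat_df$strand), , drop = FALSE]
}

#' Canonical EVE locus identifier
#'
#' `scaffold_start_end_p` / `..._m` (0-based half-open, `p`/`m` for the
#' strand). Deliberately free of newick metacharacters so locus ids can
#' serve directly as gene-tree tip labels.
#'
#' @param scaffold,start,end,strand Locus coordinates.
#' @return Character vector of ids.
#' @export
eve_locus_id <- function(scaffold, start, end, strand) {
  sprintf("%s_%d_%d_%s", scaffold, start, end,
          ifelse(strand == "+", "p", "m"))
}

.RECOGNIZED_STARTS <- c("ATG", "TTG", "CTG", "GTG")
.STOPS <- c("TAA", "TAG", "TGA")

.revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTacgtn", "TGCAtgcan", s), "")[[1]]),
        collapse = "")
}

#' ORF integrity of a locus
#'
#' Reads the hit-supported frame of the (strand-normalized) locus sequence:
#' the open reading frame runs from the first recognized start codon (ATG,
#' or alternative starts TTG/CTG/GTG) to the first subsequent stop. The
#' call is `complete` when that reading covers at least 80% of the
#' hit-supported span, `premature_stop` when an internal stop truncates
#' more than 20% of it, and `incomplete` when no start or no stop falls
#' within the locus bounds.
#'
#' @param sequence Locus nucleotide sequence (forward-strand slice of the
#'   scaffold).
#' @param strand `"+"` or `"-"`; minus-strand sequences are
#'   reverse-complemented before reading.
#' @param hit_span Length in bp of the hit-supported span (defaults to the
#'   locus length).
#' @return List with `orf_status` (one of `complete`, `premature_stop`,
#'   `incomplete`) and `start_codon` (`NA` when no start found).
#' @export
orf_integrity <- function(sequence, strand = "+", hit_span = NULL) {
  s <- toupper(as.character(sequence))
  if (nchar(s) < 6L) stop("locus sequence shorter than 6 bp")
  if (strand == "-") s <- .revcomp(s)
  if (is.null(hit_span)) hit_span <- nchar(s)
  n_cod <- nchar(s) %/% 3L
  cod <- substring(s, seq(1L, by = 3L, length.out = n_cod),
                   seq(3L, by = 3L, length.out = n_cod))
  start_idx <- which(cod %in% .RECOGNIZED_STARTS)[1]
  if (is.na(start_idx))
    return(list(orf_status = "incomplete", start_codon = NA_character_))
  stop_rel <- which(cod[-seq_len(start_idx)] %in% .STOPS)[1]
  if (is.na(stop_rel))  # ORF runs off the locus: no well-defined start
    return(list(orf_status = "incomplete", start_codon = NA_character_))
  stop_idx <- start_idx + stop_rel
  span <- (stop_idx - start_idx + 1L) * 3L
  status <- if (span >= 0.8 * hit_span) "complete" else "premature_stop"
  list(orf_status = status, start_codon = cod[start_idx])
}

#' Extract locus sequences and annotate ORF integrity in a catalog
#'
#' @param catalog EVE catalog from [call_loci()].
#' @param scaffolds Named character vector (or `DNAStringSet`) of scaffold
#'   sequences.
#' @return The catalog with `orf_status` and `start_codon` columns added.
#' @export
annotate_orf_integrity <- function(catalog, scaffolds) {
  seqs <- .coerce_alignment(scaffolds)
  catalog$orf_status <- rep(NA_character_, nrow(catalog))
  catalog$start_codon <- rep(NA_character_, nrow(catalog))
  for (i in seq_len(nrow(catalog))) {
    sc <- catalog$scaffold[i]
    if (!sc %in% names(seqs)) stop("scaffold not found: ", sc)
    sub <- substr(seqs[[sc]], catalog$start[i] + 1L, catalog$end[i])
    o <- orf_integrity(sub, catalog$strand[i])
    catalog$orf_status[i] <- o$orf_status
    catalog$start_codon[i] <- o$start_codon
  }
  catalog
}
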