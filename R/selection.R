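## Nei-Gojobori (1986) dN/dS estimation, per-family omega summaries with a
## selection-regime call, and the EVE-vs-BUSCO group comparison.

#' Pairwise dN and dS by Nei-Gojobori counting
#'
#' Counts synonymous and nonsynonymous sites and differences between two
#' in-frame codon sequences following Nei & Gojobori (1986), with
#' Jukes-Cantor multiple-hit correction. Site counts are averaged over the
#' two sequences; codons differing at more than one position are averaged
#' over all minimal mutational pathways, excluding pathways that pass
#' through a stop codon. Changes to stop codons count as nonsynonymous in
#' site counting, so S + N equals three times the number of compared codons.
#'
#' Codon pairs in which either codon contains a gap or an ambiguous base are
#' excluded pairwise-complete. Internal stop codons are an error: mask or
#' trim pseudogenized sequences first (see [family_omega()], which does
#' this automatically).
#'
#' @param seq_a,seq_b Nucleotide strings (or objects coercible via
#'   `as.character`) of equal length, a multiple of 3.
#' @return A list with elements `dN`, `dS` (Jukes-Cantor corrected; `NA`
#'   when the raw proportion is >= 3/4), `S`, `N` (site counts), `Sd`, `Nd`
#'   (difference counts) and `n_codons` (codon pairs compared).
#' @export
ng86_pairwise <- function(seq_a, seq_b) {
  ca <- split_codons(seq_a)
  cb <- split_codons(seq_b)
  if (length(ca) != length(cb))
    stop("sequences have different lengths (", 3 * length(ca), " vs ",
         3 * length(cb), ")")
  sc <- sense_codons()
  stops <- c("TAA", "TAG", "TGA")
  if (any(ca %in% stops) || any(cb %in% stops))
    stop("internal stop codon encountered; mask or trim before ng86_pairwise")
  ## gap/ambiguity exclusion is pairwise-complete
  keep <- ca %in% sc & cb %in% sc
  ca <- ca[keep]
  cb <- cb[keep]
  n <- length(ca)
  if (n == 0L)
    return(list(dN = NA_real_, dS = NA_real_, S = 0, N = 0, Sd = 0, Nd = 0,
                n_codons = 0L))
  ss <- ng_syn_sites()
  S <- (sum(ss[ca]) + sum(ss[cb])) / 2
  N <- 3 * n - S
  dm <- ng_diff_matrices()
  idx <- cbind(match(ca, sc), match(cb, sc))
  Sd <- sum(dm$sd[idx])
  Nd <- sum(dm$nd[idx])
  list(dN = jc_correct(Nd / N), dS = jc_correct(Sd / S),
       S = S, N = N, Sd = Sd, Nd = Nd, n_codons = n)
}

.mask_stop_codons <- function(seqs) {
  vapply(seqs, function(s) {
    cod <- split_codons(s)
    cod[cod %in% c("TAA", "TAG", "TGA")] <- "NNN"
    paste(cod, collapse = "")
  }, character(1))
}

#' Per-family dN/dS summary and selection-regime call
#'
#' Computes Nei-Gojobori dN/dS over all sequence pairs of a gap-free in-frame
#' codon alignment. Internal stop codons (pseudogenized copies) are masked as
#' missing codons before comparison. A pair is "defined" when its dS is
#' finite and positive; undefined pairs are excluded from the mean and
#' counted. The regime is `purifying` when a two-sided one-sample t test of
#' the defined pairwise omegas against 1 rejects at `alpha` with mean below
#' 1, `neutral` when it does not reject, and `undetermined` when fewer than
#' 3 defined pairs exist (or the test is degenerate with mean >= 1).
#'
#' @param alignment Named character vector of equal-length sequences, a
#'   `Biostrings::DNAStringSet`, or a path to a FASTA file.
#' @param family Optional family label carried into the result.
#' @param alpha Significance level for the regime test (default 0.05).
#' @return An object of class `omega_estimate`: list with `family`, `pairs`
#'   (data frame of seq_a, seq_b, dN, dS, omega), `mean_omega`, `se_omega`,
#'   `n_pairs`, `n_undefined`, `regime`.
#' @export
family_omega <- function(alignment, family = NA_character_, alpha = 0.05) {
  seqs <- .coerce_alignment(alignment)
  if (length(seqs) < 2L) stop("family_omega needs at least 2 sequences")
  seqs <- .mask_stop_codons(seqs)
  nm <- names(seqs)
  if (is.null(nm)) nm <- paste0("seq", seq_along(seqs))
  cmb <- utils::combn(length(seqs), 2)
  pairs <- data.frame(
    seq_a = nm[cmb[1, ]], seq_b = nm[cmb[2, ]],
    dN = NA_real_, dS = NA_real_, omega = NA_real_,
    stringsAsFactors = FALSE)
  for (k in seq_len(ncol(cmb))) {
    r <- ng86_pairwise(seqs[[cmb[1, k]]], seqs[[cmb[2, k]]])
    pairs$dN[k] <- r$dN
    pairs$dS[k] <- r$dS
    if (is.finite(r$dS) && r$dS > 0 && is.finite(r$dN))
      pairs$omega[k] <- r$dN / r$dS
  }
  om <- pairs$omega[is.finite(pairs$omega)]
  n_def <- length(om)
  est <- list(
    family = family, pairs = pairs,
    mean_omega = if (n_def) mean(om) else NA_real_,
    se_omega = if (n_def > 1) stats::sd(om) / sqrt(n_def) else NA_real_,
    n_pairs = nrow(pairs), n_undefined = nrow(pairs) - n_def)
  est$regime <- if (n_def < 3) {
    "undetermined"
  } else if (stats::sd(om) == 0) {
    if (mean(om) < 1) "purifying" else "neutral"
  } else {
    tt <- stats::t.test(om, mu = 1)
    if (tt$p.value < alpha && mean(om) < 1) "purifying" else "neutral"
  }
  class(est) <- "omega_estimate"
  est
}

#' @export
print.omega_estimate <- function(x, ...) {
  cat(sprintf("omega_estimate%s: mean dN/dS = %.4f (s.e. = %.4g), %d pairs (%d undefined), regime: %s\n",
              if (is.na(x$family)) "" else paste0(" [", x$family, "]"),
              x$mean_omega, x$se_omega, x$n_pairs, x$n_undefined, x$regime))
  invisible(x)
}

.coerce_alignment <- function(x) {
  if (inherits(x, "DNAStringSet")) return(as.character(x))
  if (is.character(x) && length(x) == 1L && file.exists(x))
    return(as.character(Biostrings::readDNAStringSet(x)))
  out <- as.character(x)
  names(out) <- names(x)
  out
}

#' Pooled-variance two-sample comparison of omega distributions
#'
#' Two-sided two-sample t test with pooled variance (df = n1 + n2 - 2),
#' used to compare pairwise dN/dS distributions of EVE and BUSCO gene sets.
#'
#' @param eve_omegas,busco_omegas Numeric vectors, each of length >= 2.
#' @return List with `mean_eve`, `mean_busco`, `t`, `df`, `p`.
#' @export
compare_groups <- function(eve_omegas, busco_omegas) {
  a <- eve_omegas[is.finite(eve_omegas)]
  b <- busco_omegas[is.finite(busco_omegas)]
  if (length(a) < 2L || length(b) < 2L)
    stop("both groups need at least 2 finite values")
  if (stats::var(a) == 0 && stats::var(b) == 0)
    stop("degenerate comparison: zero pooled variance")
  tt <- stats::t.test(a, b, var.equal = TRUE)
  list(mean_eve = mean(a), mean_busco = mean(b),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}
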