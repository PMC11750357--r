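## Core-gene enrichment: exact 2x2 test comparing the core-gene composition
## of an event's acquired gene set with the full repertoire of its putative
## donor virus.

#' Fisher exact test on a 2x2 contingency table
#'
#' Rows are the two gene sets (event genes vs donor-genome genes), columns
#' the core/non-core split. The odds ratio reported as primary is the
#' conditional maximum-likelihood estimate under the noncentral
#' hypergeometric model (the convention of standard statistical software);
#' the sample cross-product ratio is also returned. The two-sided p value
#' follows the point-probability rule: it sums the probabilities of all
#' tables with the observed margins whose probability does not exceed that
#' of the observed table.
#'
#' @param table 2x2 numeric matrix of non-negative counts, or a length-4
#'   vector `c(a, b, c, d)` filled by row.
#' @return List with `odds_ratio` (conditional MLE), `odds_ratio_sample`
#'   (cross-product ad/bc), `p` (two-sided), and `table`.
#' @export
fisher_exact <- function(table) {
  m <- .as_table2x2(table)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("contingency table has a zero marginal")
  ft <- stats::fisher.test(m)
  cp <- (m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1])
  list(odds_ratio = unname(ft$estimate),
       odds_ratio_sample = cp,
       p = ft$p.value,
       table = m)
}

.as_table2x2 <- function(table) {
  if (is.matrix(table)) {
    if (!all(dim(table) == c(2L, 2L))) stop("table must be 2x2")
    m <- table
  } else if (length(table) == 4L) {
    m <- matrix(as.numeric(table), 2, 2, byrow = TRUE)
  } else stop("table must be a 2x2 matrix or a length-4 vector")
  if (any(m < 0) || any(m != round(m))) stop("counts must be non-negative integers")
  m
}

#' Core-gene enrichment for an endogenization event
#'
#' Builds the 2x2 table (event genes core/non-core vs donor repertoire
#' core/non-core) from a virus panel and runs [fisher_exact()].
#'
#' @param event_families Character vector of gene families in the event.
#' @param donor_repertoire Data frame with columns `family` and `core`
#'   (logical): the full gene repertoire of the putative donor virus.
#' @return List with the table, counts, and the `fisher_exact` result.
#' @export
core_gene_enrichment <- function(event_families, donor_repertoire) {
  stopifnot(is.data.frame(donor_repertoire),
            all(c("family", "core") %in% names(donor_repertoire)))
  core_map <- stats::setNames(donor_repertoire$core, donor_repertoire$family)
  known <- event_families[event_families %in% names(core_map)]
  a <- sum(core_map[known])          # event, core
  b <- length(known) - a             # event, non-core
  cc <- sum(donor_repertoire$core)   # donor repertoire, core
  d <- nrow(donor_repertoire) - cc   # donor repertoire, non-core
  tab <- matrix(c(a, b, cc, d), 2, 2, byrow = TRUE,
                dimnames = list(c("event", "donor"), c("core", "non_core")))
  res <- fisher_exact(tab)
  c(list(n_event = length(known), n_event_core = a,
         n_donor = nrow(donor_repertoire), n_donor_core = cc), res)
}
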