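## Continuous-time codon evolution: single-omega (M0-like) Gillespie
## simulation along a guide tree with HKY-style transition/transversion
## bias. Substitutions to stop codons are disallowed, so simulated
## sequences are stop-free unless pseudogenization is applied afterwards.

## Neighbor structure and rates for the 61 sense codons under (omega,
## kappa). Rates are normalized so that one unit of branch length equals
## one expected substitution per codon for a uniform sense-codon state.
.codon_rates <- function(omega, kappa) {
  key <- paste0("rates_", format(omega, digits = 10), "_",
                format(kappa, digits = 10))
  if (!is.null(.weve[[key]])) return(.weve[[key]])
  gc <- .genetic_code()
  sc <- sense_codons()
  n <- length(sc)
  neighbors <- rates <- vector("list", n)
  for (i in seq_len(n)) {
    cod <- sc[i]
    nb <- integer(0)
    rt <- numeric(0)
    for (pos in 1:3) {
      base <- substr(cod, pos, pos)
      for (alt in setdiff(.NUC, base)) {
        mut <- cod
        substr(mut, pos, pos) <- alt
        if (gc[mut] == "*") next
        r <- 1
        if (.is_transition(base, alt)) r <- r * kappa
        if (gc[mut] != gc[cod]) r <- r * omega
        nb <- c(nb, match(mut, sc))
        rt <- c(rt, r)
      }
    }
    neighbors[[i]] <- nb
    rates[[i]] <- rt
  }
  total <- vapply(rates, sum, numeric(1))
  norm <- mean(total)
  res <- list(neighbors = neighbors,
              rates = lapply(rates, function(r) r / norm),
              total = total / norm)
  .weve[[key]] <- res
  res
}

.evolve_branch <- function(states, len, rt) {
  if (len <= 0) return(states)
  t <- stats::rexp(length(states), rt$total[states])
  active <- which(t < len)
  while (length(active)) {
    for (i in active) {
      s <- states[i]
      nb <- rt$neighbors[[s]]
      states[i] <- if (length(nb) == 1L) nb else
        nb[sample.int(length(nb), 1L, prob = rt$rates[[s]])]
    }
    t[active] <- t[active] + stats::rexp(length(active),
                                         rt$total[states[active]])
    active <- active[t[active] < len]
  }
  states
}

#' Simulate an in-frame codon alignment along a guide tree
#'
#' Gillespie simulation of a single-omega codon substitution process:
#' every single-nucleotide change has base rate 1, multiplied by `kappa`
#' for transitions and by `omega` for nonsynonymous changes; changes to
#' stop codons are forbidden. Branch lengths are in expected substitutions
#' per codon (for a uniform sense-codon state). The root sequence is drawn
#' uniformly over sense codons, so the alignment is gap-free and free of
#' internal stops.
#'
#' @param guide_tree An `ape::phylo` with branch lengths, or a single tip
#'   label (returns one random sequence).
#' @param omega dN/dS of the process (> 0).
#' @param kappa Transition/transversion rate ratio.
#' @param n_codons Number of codons (>= 50).
#' @param seed Optional integer seed (otherwise the current RNG stream is
#'   used).
#' @return Named character vector of tip sequences, each `3 * n_codons`
#'   long.
#' @export
simulate_codon_alignment <- function(guide_tree, omega, kappa = 1.5,
                                     n_codons = 200L, seed = NULL) {
  stopifnot(omega > 0, n_codons >= 50L)
  if (!is.null(seed)) set.seed(seed)
  sc <- sense_codons()
  rt <- .codon_rates(omega, kappa)
  root_states <- sample.int(length(sc), n_codons, replace = TRUE)
  if (is.character(guide_tree) && length(guide_tree) == 1L) {
    out <- paste(sc[root_states], collapse = "")
    return(stats::setNames(out, guide_tree))
  }
  tree <- guide_tree
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  states <- vector("list", ntip + tree$Nnode)
  states[[root]] <- root_states
  ## cladewise order guarantees parents are visited before children
  tree <- ape::reorder.phylo(tree, "cladewise")
  for (k in seq_len(nrow(tree$edge))) {
    p <- tree$edge[k, 1]
    ch <- tree$edge[k, 2]
    states[[ch]] <- .evolve_branch(states[[p]], tree$edge.length[k], rt)
  }
  out <- vapply(seq_len(ntip), function(i)
    paste(sc[states[[i]]], collapse = ""), character(1))
  stats::setNames(out, tree$tip.label)
}

#' Insert a premature stop codon into an in-frame sequence
#'
#' Replaces the codon at the given relative position with `TAA`,
#' emulating pseudogenization of an EVE copy.
#'
#' @param sequence In-frame nucleotide string.
#' @param at_frac Relative position of the stop (default 0.45).
#' @return The pseudogenized sequence.
#' @export
pseudogenize <- function(sequence, at_frac = 0.45) {
  cod <- split_codons(sequence)
  idx <- max(2L, min(length(cod) - 1L, floor(length(cod) * at_frac)))
  cod[idx] <- "TAA"
  paste(cod, collapse = "")
}
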