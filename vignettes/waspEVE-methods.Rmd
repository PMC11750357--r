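---
title: "Inferring filamentovirus endogenization events: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring filamentovirus endogenization events: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(waspEVE)
```

## The problem

Some endoparasitoid wasps have stably integrated large parts of a viral
genome into their own chromosomes and now use the retained ("domesticated")
viral genes to build virus-like particles that protect their eggs inside
the host. `waspEVE` implements the comparative-genomic side of that story
for filamentoviruses in cynipoid (figitid) wasps: given genome scaffolds,
viral-protein homology hits, per-gene phylogenies, codon alignments and a
calibrated species chronogram, it

1. catalogs candidate endogenous viral elements (EVEs) and scores the
   evidence that they sit on genuine wasp chromosomes rather than on
   contaminating viral sequence,
2. classifies each viral gene family's phylogeny into topology types that
   distinguish one ancestral endogenization from a second, lineage-specific
   one,
3. groups loci into endogenization *events* by transitive scaffold
   colocation combined with shared supported clades,
4. tests whether an event's acquired gene set is enriched for viral core
   genes,
5. estimates dN/dS per family and calls a selection regime, and
6. brackets each event's age on the chronogram.

Because the real genome assemblies are large and external, the package
ships a synthetic-scenario generator (`generate_scenario()`,
`study_mimic_scenario()`) that emulates every input file with a
machine-readable truth table, so each stage - and the pipeline end to end -
is tested against known ground truth.

## Integration evidence

A candidate scaffold is accepted as chromosomally integrated
(`classify_scaffold()`) when any of three signals holds:

* **GC and coverage inside the BUSCO envelope.** For each species the
  scaffolds carrying BUSCO genes define a robust envelope per metric:
  median ± *k*·MAD, with the raw MAD (consistency constant 1) and *k* = 5
  by default. The published analysis compared these distributions visually;
  the per-scaffold envelope is our operationalization, and *k* is exposed
  because the right width depends on how skewed a real assembly's coverage
  is. With fewer than 5 BUSCO scaffolds the envelope is refused rather than
  guessed.
* **At least one eukaryotic predicted gene.** Contig taxonomy is a strict
  majority vote over the taxonomic labels of the scaffold's predicted
  proteins; ties and empty label sets give `"unassigned"` - the
  conservative choice, since a false eukaryotic label would fabricate
  integration evidence.
* **At least one transposable-element interval** after filtering (e-value
  strictly below 1e-10 *and* alignment length strictly above 100 aa) and
  merging overlapping hits. All interval arithmetic is 0-based half-open,
  and book-ended intervals (end == start) merge; one convention, stated
  once, tested at the boundaries.

A scaffold with none of these is `likely_exogenous`; `ambiguous` is
reserved for scaffolds whose GC or coverage could not be measured.

## The EVE catalog

Homology hits arrive in 12-column tabular form; minus-strand hits are
normalized at parse time. Hits survive an inclusive e-value ceiling of
1e-3 (`filter_hits()`), and overlapping same-scaffold, same-strand hits
are merged into one locus by interval union regardless of family
(`call_loci()`); the locus takes the family of its best-bitscore hit, with
ties broken by lower e-value and then lexicographic subject id. The
upstream study delegated its clustering step to an external pipeline, so
this merge rule is this package's explicit, tested reconstruction.

ORF integrity (`orf_integrity()`) reads the hit-supported frame of the
strand-normalized locus: the ORF runs from the first recognized start
codon - ATG or the alternative starts TTG, CTG, GTG, which are real
features of filamentovirus *lef-5* - to the first subsequent stop. A
reading covering at least 80% of the hit-supported span is `complete`; an
internal stop truncating more than 20% is `premature_stop`; a locus with
no start or no stop inside its bounds is `incomplete` (its start codon is
reported as `NA`, since any start found in a truncated reading is
arbitrary). The 80% threshold quantifies what the source material treats
qualitatively; it is a package choice, not a measured constant.

## Topology types

Gene trees carry `"aLRT/UFboot"` internal labels; `parse_support()` uses
the ultrafast-bootstrap (second) component, and the classification
threshold is a *strict* \> 80 on that component. Whether the published
threshold referred to UFboot, aLRT or both is not stated in the source;
UFboot is the default and the component choice is a configuration knob.

Trees are rooted on hytrosavirus outgroup tips when present, else
midpoint-rooted; support labels are handled as *edge* labels so re-rooting
cannot detach them from their bipartitions. `wasp_clades()` finds maximal
all-wasp clades with support \> 80, decomposing unsupported ones down to
singleton tips, which count as clades with vacuously sufficient support -
necessary because the lineage-specific pattern can rest on a single
sequence. `nearest_viral_relative()` takes the majority lineage among the
sister group's virus tips, walking rootward past wasp-only sisters (the
walk is recorded).

`classify_gene_tree()` then calls:

* **TYPE_I** - one supported clade containing every wasp tip, nearest
  relative LhFV-like: the ancestral event's signature.
* **TYPE_II** - every wasp tip in one single-species clade, nearest
  relative LbFV-like: the *Rhoptromeris*-specific event.
* **TYPE_III** - both patterns in one tree (families acquired twice).
* **UNCLASSIFIED** - anything else: unsupported clades, nearest relatives
  outside the two canonical lineages (reported as `"other"`, never
  guessed), or clade configurations outside the three patterns.

The rules are written against clade/lineage structure, not root position
inside the virus backbone, and the tests check invariance to rotation and
re-serialization plus equivalence with a brute-force clade enumerator on
random small trees.

## From loci to events

The grouping logic is a graph closure. Nodes are catalog loci; edges are

* **colocation** - two loci on the same scaffold of the same species, and
* **homology-clade** - two same-family loci inside the same supported wasp
  clade of that family's tree (UNCLASSIFIED families contribute none).

Connected components, found by union-find, are the events: if A and B
colocalize in one species and B and C in another, all three belong to one
ancestral event. Homology-clade edges encode the aggregation of copies
across genomes even without colocation in the second assembly. Singleton
components of unclassifiable families are reported as *unassigned loci*,
not one-locus events. Each event's donor lineage is the majority over its
member families' nearest-relative tags, taken from the clade that actually
contains the member loci; disagreement raises a `conflict` flag and is
never auto-resolved. Paralogous copies are distinct nodes throughout;
family deduplication happens only in the summary.

## Core-gene enrichment

`fisher_exact()` tests the 2x2 table (event genes vs donor-repertoire
genes, core vs non-core). The primary odds ratio is the conditional
maximum-likelihood estimate under the noncentral hypergeometric model -
the convention of standard statistical software, and the one that matches
published values - with the sample cross-product also reported. The
two-sided p follows the point-probability rule (sum over tables no more
probable than the observed one); two-sided conventions differ enough that
this is stated explicitly, and the test suite checks the p value against a
full hypergeometric enumeration for every table with total up to 40.

On the worked table of 12 core among 18 event genes against a 110-gene
donor repertoire with 29 core genes, the package computes an odds ratio of
5.50 and p = 0.001753 (the acceptance tests assert exactly this).

## dN/dS and selection regimes

`ng86_pairwise()` implements Nei-Gojobori (1986) counting with
Jukes-Cantor correction. The source never names its dN/dS method; NG86 is
chosen because it is fully specifiable from the sequences alone, and users
should not expect maximum-likelihood (codeml-style) values to match it
numerically. Conventions, each tested:

* site counts are averaged over the two sequences; changes to stop codons
  count as nonsynonymous, so S + N = 3·(codons compared) exactly;
* codons differing at 2-3 positions are averaged over all minimal
  mutational pathways, excluding pathways through stops;
* proportions are corrected by d = -(3/4)·ln(1 - (4/3)p), undefined at
  p >= 3/4 (the pair is excluded and counted);
* gap/ambiguous codons are excluded pairwise-complete, and internal stop
  codons are an error at the estimator level - `family_omega()` masks
  stops (pseudogenized copies) as missing codons before comparing.

`family_omega()` averages omega over defined pairs (dS \> 0) and calls
`purifying` when a two-sided one-sample t test against 1 rejects at
alpha = 0.05 with mean \< 1, `neutral` when it does not reject, and
`undetermined` with fewer than 3 defined pairs (matching the "too few
sequences" annotation in the source's figure). Whether published standard
errors are over pairs or over sequences is unstated; over pairs is this
package's convention. `compare_groups()` is the pooled-variance two-sample
t (df = n1 + n2 - 2) over pooled pairwise omegas of EVE vs BUSCO genes.

## Event dating

`date_event()` refuses to invent point estimates. An event is bracketed by
the crown age of the MRCA of its recipient species (0 for a single
species) below, and the age of the split from the closest EVE-negative
relative above, with credibility intervals propagated from node
annotations. The fixture chronogram (`cynipoid_chronogram()`) carries the
three literature ages that matter - the *Ganaspis* split at 91.1 Myr, the
crown of the six EVE-positive species at 76.4 Myr (CI 55-100), and the
*Rhoptromeris*-*Trichoplasta* split at 40 Myr (CI 22-59) - while the
remaining node ages (Synergus 130, Leptolamina 85, the *Leptopilina*
crown 20, *L. heterotoma*-*L. clavipes* 12) are synthetic placeholders,
and the shipped file is named accordingly. The source prints both "76.4"
and "approximately 76 (55-100)" for the same node; the fixture stores 76.4
with CI 55-100. Node ages travel as newick node labels, `age` or
`age_lo_hi` (underscores), a deliberately trivial dialect documented in
`read_chronogram()`.

## The synthetic generator

`generate_scenario()` turns a `scenario_config()` - species chronogram,
virus panel with per-virus gene repertoires and core flags, event
specifications, genome/coverage parameters, support-noise ranges, and
per-family omega - into the full input file set plus truth tables. Design
choices:

* **Structure is planted, noise is seeded.** Which loci exist, where they
  colocate, which families are shared, which copies are pseudogenized, and
  which trees are unclassifiable are all determined by the event specs;
  the seed only moves sequences, branch lengths, support draws and
  coordinates. True-clade UFboot is drawn from 91-100 and spurious from
  40-79, strictly straddling the \> 80 rule, so classification counts do
  not depend on the seed. Identical seeds regenerate byte-identical
  datasets.
* **Codon model.** A single-omega (M0-like) Gillespie simulation along
  branches: every single-nucleotide change has base rate 1, times kappa
  for transitions, times omega for nonsynonymous changes; changes to stops
  are forbidden; rates are normalized so branch lengths are expected
  substitutions per codon. This is the simplest model under which NG86 is
  approximately unbiased. NG86 ignores transition/transversion bias in its
  site counts, so its omega estimate drifts low as kappa grows; measured
  over 100 replicates of 300 codons on a 4-tip tree, the relative bias is
  under 6% at kappa = 1, about 9-10% at kappa = 1.5 and 11-15% at
  kappa = 2. The generator's default kappa is **1.5**: a realistic
  transition bias that keeps the estimator within its 15% calibration
  band with margin. Pseudogenization inserts a TAA at ~45% of the coding
  length after simulation.
* **Viral inserts match host composition by default** (insert GC offset
  0), so envelope-based evidence passes; a nonzero offset is available to
  build negative controls. Scaffolds are tens of kilobases and a few dozen
  per species, keeping the full scenario generation plus pipeline run
  under ~10 seconds on one CPU.
* **The study-mimic scenario** (`study_mimic_scenario()`) plants 153 loci
  over six positive species: an ancestral 18-family event from an
  LhFV-like donor at the crown of the six, a recent 9-family event from an
  LbFV-like donor on the *Rhoptromeris* branch (16 copies, 7 with
  premature stops or truncations), 5 families in both, one family per
  event emitting an unclassifiable tree (assignable only through
  colocation, as happened in the real analysis), and 3 orphan loci whose
  nearest relatives are non-canonical filamentoviruses and which sit alone
  on their scaffolds - so transitive closure recovers exactly two events
  and 150 of 153 assigned loci. Per-species locus counts are a plausible
  allocation summing to the planted totals; they do not reproduce the real
  per-genome counts, which depend on the actual assemblies.

### What passing the mimic does and does not show

The generator emulates the *structure* of the real inputs (formats,
support-label dialect, colocation patterns, pseudogenization, codon
evolution at specified omega), not their noise: alignments are gap-free,
hits are planted rather than found by a search engine, scaffold background
is i.i.d. sequence, and support values are draws from configured ranges
rather than resampling artifacts. Recovery of the planted scenario
therefore validates the pipeline's logic and conventions, not its
robustness to assembly error, alignment ambiguity or search-engine
idiosyncrasies. Quantities tied to the real assemblies - per-genome EVE
counts, the 55-of-107 scaffolds with eukaryotic genes or TEs, the
1000-plus-df EVE-vs-BUSCO comparison, and any site-level selection
classification (which would need ML site models) - are out of scope by
design and are absent from the outputs.

## Problem sizes and numerical choices

The shipped scenario uses 200-codon alignments, ~260 scaffolds of 6-30 kb
across nine species, and 25 gene trees; the full generation-plus-pipeline
cycle runs in seconds, and the complete test suite (including a full
Fisher enumeration to table total 40 and a 120-replicate omega-recovery
sweep) in about a minute. Degenerate inputs are handled explicitly:
zero-event scenarios produce empty catalogs and clean exits; zero branch
lengths produce identical sequences; dS = 0 pairs are excluded and
counted; a degenerate (zero-variance) group comparison is an error rather
than a p value; chronograms with non-decreasing ages are rejected naming
the offending nodes. Ties are broken deterministically everywhere
(bitscore, then e-value, then subject id for locus families; lexicographic
order for event numbering), so identical inputs give identical outputs.
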